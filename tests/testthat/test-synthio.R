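test_that("pathway simulation realises the requested crosstalk structure", {
    # zero overlap: no gene belongs to two pathways
    cfg0 <- simConfig(nGenes = 400, nPathways = 6, crosstalkOverlap = 0,
                      seed = 3)
    pw0 <- simulatePathways(cfg0)
    all_genes <- unlist(pathwayGenes(pw0))
    expect_equal(anyDuplicated(all_genes), 0L)

    # two pathways of 10 with 20% overlap: union is 10 + 10 - 2 = 18
    cfg2 <- simConfig(nGenes = 100, nPathways = 2,
                      pathwaySizeRange = c(10, 10), crosstalkOverlap = 0.2,
                      nDysregulated = 0, nModules = 0, seed = 5)
    pw2 <- simulatePathways(cfg2)
    expect_equal(length(unique(unlist(pathwayGenes(pw2)))), 18L)
    expect_equal(length(intersect(pathwayGenes(pw2, "P01"),
                                  pathwayGenes(pw2, "P02"))), 2L)

    # every edge endpoint is a member, and each pathway graph is connected
    pwd <- simulatePathways(simConfig(seed = 9))
    ed <- pathwayEdges(pwd)
    for (p in pathwayIds(pwd)) {
        g <- pathwayGenes(pwd, p)
        e <- ed[ed$pathway == p, ]
        expect_true(all(c(e$from, e$to) %in% g))
        gr <- igraph::graph_from_data_frame(e[, c("from", "to")],
                                            directed = FALSE, vertices = g)
        expect_true(igraph::is_connected(gr))
    }

    # oversized overlap is rejected
    expect_error(simulatePathways(
        simConfig(nPathways = 5, pathwaySizeRange = c(10, 10),
                  crosstalkOverlap = 0.6)), "crosstalkOverlap")
})

test_that("generator output is byte-identical under a fixed configuration", {
    cfg <- simConfig(nGenes = 300, nLnc = 60, nPathways = 6, nCase = 20,
                     nControl = 20, moduleSize = 60, seed = 42)
    d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
    writeSimulation(simulateCrosstalkStudy(cfg), d1)
    writeSimulation(simulateCrosstalkStudy(cfg), d2)
    for (f in list.files(d1)) {
        expect_identical(unname(tools::md5sum(file.path(d1, f))),
                         unname(tools::md5sum(file.path(d2, f))),
                         label = paste("md5 of", f))
    }
    unlink(c(d1, d2), recursive = TRUE)
})

test_that("planted truth is consistent and null planting leaves truth empty", {
    sim <- simulateCrosstalkStudy(simConfig(seed = 4))
    tr <- sim$truth
    cm <- assayOf(sim$mrna)
    expect_true(all(cm >= 0))
    expect_true(is.integer(cm))

    # conservation: truth ids exist in the emitted universe; modules disjoint
    asg <- unlist(tr$module_assignments)
    expect_true(all(names(asg) %in% c(rownames(sim$mrna),
                                      rownames(sim$lnc))))
    expect_equal(anyDuplicated(names(asg)), 0L)
    expect_true(all(tr$affected_genes %in% rownames(sim$mrna)))
    expect_true(all(names(unlist(tr$de_lnc)) %in% rownames(sim$lnc)))

    # prognostic genes are crosstalk genes and members of module 1
    dysGenes <- unlist(pathwayGenes(sim$pathways)[tr$dysregulated_pathway_ids])
    expect_true(all(tr$prognostic_genes %in% dysGenes))
    expect_equal(unname(asg[tr$prognostic_genes]), c("M1", "M1"))

    # null planting
    sim0 <- simulateCrosstalkStudy(simConfig(effectDelta = 0,
                                             lncDeFraction = 0, seed = 4))
    expect_length(sim0$truth$affected_genes, 0)
    expect_length(unlist(sim0$truth$de_lnc), 0)
})

test_that("planted expression shifts land near the configured effect size", {
    sim <- simulateCrosstalkStudy(simConfig(seed = 6))
    tr <- sim$truth
    y <- normLog2(assayOf(sim$mrna))
    grp <- groupsOf(sim$mrna)
    lfc <- rowMeans(y[tr$affected_genes, grp == "AD"]) -
        rowMeans(y[tr$affected_genes, grp == "control"])
    expect_lt(abs(mean(lfc) - 1.0), 0.2)
})

test_that("survival generation follows the proportional-hazards planting", {
    cfg <- simConfig(nCase = 300, seed = 8)
    sim <- simulateCrosstalkStudy(cfg)
    sv <- sim$survival
    expect_true(all(sv$time_years >= 0))
    expect_true(all(sv$event %in% 0:1))
    expect_true(all(sv$braaksc %in% 0:6))
    expect_true(all(sv$ceradsc %in% 1:4))
    expect_true(all(sv$dcfdx_lv %in% 1:6))

    # protective coefficients: joint high expression of the planted genes
    # means stochastically later events
    z <- t(scale(t(log2(assayOf(sim$mrna)[
        sim$truth$prognostic_genes, sv$sample] + 1))))
    lp <- as.numeric(crossprod(z, cfg@prognosticCoefs))
    ev <- sv$event == 1
    expect_gt(cor(lp[ev], sv$time_years[ev], method = "spearman") * -1, 0.2)

    # degenerate censoring horizon: everything censored at time zero
    sim0 <- simulateCrosstalkStudy(simConfig(censorHorizon = 0, nCase = 30,
                                             seed = 8))
    expect_true(all(sim0$survival$time_years == 0))
    expect_equal(sum(sim0$survival$event), 0)

    # prognostic gene missing from the matrix is a generation error
    bad <- sim$truth
    bad$prognostic_genes <- c("NOPE1", "NOPE2")
    expect_error(simulateSurvival(cfg, sim$mrna, bad), "missing")
})
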