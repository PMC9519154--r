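twoPathways <- function() {
    # P1 and P2 of 10 members sharing exactly one gene
    g1 <- paste0("a", 1:10)
    g2 <- c("a10", paste0("b", 1:9))
    e1 <- data.frame(pathway = "P1", from = g1[-10], to = g1[-1])
    e2 <- data.frame(pathway = "P2", from = g2[-10], to = g2[-1])
    PathwayCollection(c("P1", "P2"), list(g1, g2), edges = rbind(e1, e2))
}

test_that("global network is the deduplicated union of pathway graphs", {
    net <- buildGlobalNetwork(twoPathways())
    expect_equal(length(networkNodes(net)), 19L)
    expect_true(Matrix::isSymmetric(net@adjacency))
    cs <- Matrix::colSums(net@transition)
    expect_equal(unname(cs[cs > 0]), rep(1, sum(cs > 0)), tolerance = 1e-12)

    # an edge listed in two pathways collapses to one adjacency entry
    pc <- PathwayCollection(
        c("X", "Y"), list(c("g1", "g2"), c("g1", "g2")),
        edges = data.frame(pathway = c("X", "Y"),
                           from = c("g1", "g1"), to = c("g2", "g2")))
    net2 <- buildGlobalNetwork(pc)
    expect_equal(as.numeric(net2@adjacency["g1", "g2"]), 1)
    expect_equal(Matrix::nnzero(net2@adjacency), 2)

    expect_error(buildGlobalNetwork(
        PathwayCollection(character(0), list())), "empty")
})

test_that("t-scores behave under symmetry and degeneracy", {
    set.seed(1)
    x <- matrix(rnorm(200), 10, 20,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:20)))
    grp <- rep(c("AD", "control"), each = 10)
    t1 <- tScores(x, grp)
    t2 <- tScores(x, rev(grp))
    expect_equal(unname(t1), unname(-t2), tolerance = 1e-12)
    x["g1", ] <- 5
    expect_equal(unname(tScores(x, grp)["g1"]), 0)
})

test_that("random walk with restart matches closed forms and linear solves", {
    # 2-node path, r = 0.5, seeded entirely on node A: P_inf = (2/3, 1/3)
    pc <- PathwayCollection("P", list(c("A", "B")),
                            edges = data.frame(pathway = "P",
                                               from = "A", to = "B"))
    net <- buildGlobalNetwork(pc)
    infl <- rwrGDS(net, c(A = 1, B = 0), r = 0.5)
    expect_equal(infl$p_inf, c(2 / 3, 1 / 3), tolerance = 1e-9)
    expect_equal(sum(infl$p0), 1)
    expect_equal(sum(infl$p_inf), 1, tolerance = 1e-8)

    # min-max normalisation of the stationary vector
    gds <- (c(0.2, 0.5, 0.3) - 0.2) / (0.5 - 0.2)
    expect_equal(gds, c(0, 1, 1 / 3))
    expect_equal(range(infl$gds), c(0, 1))

    # iterative solution equals the direct linear solve on random graphs
    set.seed(7)
    for (rep in 1:3) {
        n <- sample(20:200, 1)
        g <- igraph::sample_gnp(n, 3 / n)
        g <- igraph::add_edges(g, rbind(1:(n - 1), 2:n))  # force connected
        el <- igraph::as_edgelist(g)
        nodes <- paste0("n", seq_len(n))
        pc <- PathwayCollection("P", list(nodes),
            edges = data.frame(pathway = "P", from = nodes[el[, 1]],
                               to = nodes[el[, 2]]))
        net <- buildGlobalNetwork(pc)
        tv <- setNames(abs(rnorm(n)), networkNodes(net))
        infl <- rwrGDS(net, tv, r = 0.7, tol = 1e-14)
        p0 <- infl$p0
        direct <- rwrLinearSolve(net@transition, p0, 0.7)
        expect_lt(max(abs(infl$p_inf - direct)), 1e-8)
    }

    expect_error(rwrGDS(net, setNames(rep(0, n), networkNodes(net))),
                 "zero")
    # uniform seeding is available regardless of the t profile
    u <- rwrGDS(net, setNames(rep(0, n), networkNodes(net)), p0 = "uniform")
    expect_equal(sum(u$p_inf), 1, tolerance = 1e-8)
})

test_that("gene ranking orders by weight with deterministic tie-breaks", {
    infl <- data.frame(gene = paste0("g", 1:4), gds = c(1, 1, 0, 0))
    tv <- c(g1 = 2, g2 = -2, g3 = 2, g4 = 0)
    rk <- rankGenes(tv, infl)
    # g1,g2 tie at 4 (lexicographic), then g3 at 2, zero-t gene last
    expect_equal(rk$gene, c("g1", "g2", "g3", "g4"))
    expect_equal(rk$weight, c(4, 4, 2, 0))
})

test_that("running-sum pathway score equals the brute-force oracle", {
    rk <- data.frame(gene = paste0("g", 1:4), t = c(4, 3, 2, 1),
                     gds = 0, weight = c(4, 3, 2, 1))
    ps <- pathwayScore(rk, c("g1", "g2"))
    expect_equal(ps$score, 1.0)
    expect_equal(ps$peak_index, 2L)
    expect_equal(ps$gene_pct, 0.5)
    expect_equal(ps$tag_pct, 1.0)
    expect_equal(ps$signal, 1.0)

    # members at the bottom of the list score negative
    expect_lt(pathwayScore(rk, c("g3", "g4"))$score, 0)

    # degenerate cases are skipped with a warning
    expect_warning(expect_null(pathwayScore(rk, c("x", "y"))))
    rk0 <- rk; rk0$weight <- c(0, 0, 1, 1)
    expect_warning(expect_null(pathwayScore(rk0, c("g1", "g2"))))

    # random instances: exact equality with the positional oracle and
    # scores always inside [-1, 1]
    set.seed(3)
    for (rep in 1:20) {
        n <- sample(20:80, 1)
        rkr <- data.frame(gene = paste0("g", 1:n), t = 0, gds = 0,
                          weight = sort(abs(rnorm(n)), decreasing = TRUE))
        members <- sample(rkr$gene, sample(3:10, 1))
        got <- pathwayScore(rkr, members)
        want <- bruteForceScore(rkr, members)
        expect_equal(got$score, want$score, tolerance = 1e-12)
        expect_equal(got$peak_index, want$peak_index)
        expect_gte(got$score, -1)
        expect_lte(got$score, 1)
    }
})

test_that("permutation scoring flags planted pathways and stays calibrated", {
    cfg <- simConfig(nCase = 40, nControl = 40, seed = 31)
    sim <- simulateCrosstalkStudy(cfg)
    expr <- tpmNormalize(cpmFilter(sim$mrna), log = TRUE)
    grp <- groupsOf(sim$mrna)
    res <- suppressWarnings(pagiScore(expr, grp, sim$pathways, B = 200,
                                      seed = 1))
    sc <- pathwayScores(res)
    planted <- sim$truth$dysregulated_pathway_ids
    # planted pathways reach the smallest attainable permutation p
    expect_true(all(sc$perm_p[sc$pathway_id %in% planted] <=
                        1 / 201 + 1e-12))
    expect_true(all(sc$fdr >= sc$perm_p, na.rm = TRUE))

    # monotonicity: a stronger planted shift does not lower the mean
    # planted score (same seed)
    cfgLo <- simConfig(nCase = 40, nControl = 40,
                       effectDelta = 0.5, seed = 31)
    simLo <- simulateCrosstalkStudy(cfgLo)
    exprLo <- tpmNormalize(cpmFilter(simLo$mrna), log = TRUE)
    tLo <- tScores(exprLo, groupsOf(simLo$mrna))
    netLo <- buildGlobalNetwork(simLo$pathways)
    rkLo <- rankGenes(tLo, rwrGDS(netLo, tLo))
    tHi <- tScores(expr, grp)
    net <- buildGlobalNetwork(sim$pathways)
    rkHi <- rankGenes(tHi, rwrGDS(net, tHi))
    mLo <- mean(vapply(planted, function(p)
        pathwayScore(rkLo, pathwayGenes(simLo$pathways, p))$score,
        numeric(1)))
    mHi <- mean(vapply(planted, function(p)
        pathwayScore(rkHi, pathwayGenes(sim$pathways, p))$score,
        numeric(1)))
    expect_gte(mHi, mLo)

    # too few permutations for the FDR cut is warned about
    expect_warning(pagiScore(expr, grp, sim$pathways, B = 50, seed = 1),
                   "cannot reach")

    # planted affected genes out-score the rest on average
    tv <- abs(tHi)
    aff <- intersect(sim$truth$affected_genes, names(tv))
    expect_gt(mean(tv[aff]), mean(tv[setdiff(names(tv), aff)]))
})
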