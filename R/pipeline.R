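#' Default pipeline configuration
#'
#' One structured list governing every stage, defaulting to the standard
#' thresholds: CPM 1 in 50% of samples, DE lncRNA p < 0.05 and
#' |log2FC| > 0.5, pathway FDR < 0.01, scale-free fit R^2 > 0.85,
#' minimum module size 50, eigengene merge height 0.25, univariate Cox
#' p < 0.01. The `sim` section mirrors [simConfig()].
#'
#' @param file optional YAML file whose entries override the defaults
#'   (section by section).
#' @return nested configuration list.
#' @export
pipelineConfig <- function(file = NULL) {
    cfg <- list(
        sim = as.list(formals(simConfig)[c(
            "nGenes", "nLnc", "nPathways", "crosstalkOverlap",
            "nDysregulated", "effectDelta", "affectedFraction",
            "nCase", "nControl", "nBatches", "nbDispersion", "nModules",
            "moduleSize", "moduleFactorSd", "lncDeFraction", "lncDeLfc",
            "baselineHazard", "censorHorizon", "batchEffectSd", "seed")]),
        preprocess = list(cpm_threshold = 1, cpm_frac = 0.5),
        de = list(p = 0.05, lfc = 0.5),
        # 1000 permutations: with B permutations and n pathways of which k
        # carry signal, the smallest attainable BH-adjusted FDR is
        # n/(k*(B+1)); 200 would place FDR < 0.01 out of reach
        pagi = list(restart = 0.7, permutations = 1000L, fdr = 0.01),
        crosstalk = list(min_autophagy = 5L, top_k = 20L),
        coexpr = list(min_module_size = 50L, merge_height = 0.25,
                      r2 = 0.85),
        cox = list(uni_p = 0.01, times = c(3, 5), ref_time = 5))
    cfg$sim$pathwaySizeRange <- eval(formals(simConfig)$pathwaySizeRange)
    cfg$sim$prognosticCoefs <- eval(formals(simConfig)$prognosticCoefs)
    if (!is.null(file)) {
        user <- yaml::read_yaml(file)
        for (sec in names(user))
            for (key in names(user[[sec]]))
                cfg[[sec]][[key]] <- user[[sec]][[key]]
    }
    cfg
}

# stage registry: declared inputs/outputs drive dependency checking
pipelineStages <- function() list(
    simulate = list(
        inputs = character(0),
        outputs = c("mrna_counts.tsv", "lnc_counts.tsv", "pheno.tsv",
                    "survival.tsv", "pathways.gmt", "pathway_edges.tsv",
                    "gene_lengths.tsv", "autophagy_genes.txt", "truth.json")),
    preprocess = list(
        inputs = c("mrna_counts.tsv", "pheno.tsv", "gene_lengths.tsv"),
        outputs = "mrna_expr.tsv"),
    delnc = list(
        inputs = c("lnc_counts.tsv", "pheno.tsv"),
        outputs = "de_lncrna.tsv"),
    pagi = list(
        inputs = c("mrna_expr.tsv", "pheno.tsv", "pathways.gmt",
                   "pathway_edges.tsv"),
        outputs = c("pathway_scores.tsv", "gene_influence.tsv")),
    crosstalk = list(
        inputs = c("pathway_scores.tsv", "gene_influence.tsv",
                   "pathways.gmt", "autophagy_genes.txt", "mrna_expr.tsv"),
        outputs = c("feature_pathways.tsv", "feature_mrnas.txt",
                    "pathway_gene_network.tsv")),
    coexpr = list(
        inputs = c("mrna_expr.tsv", "feature_mrnas.txt", "de_lncrna.tsv",
                   "lnc_counts.tsv", "pheno.tsv"),
        outputs = c("modules.tsv", "eigengenes.tsv",
                    "soft_threshold_scan.tsv")),
    enrich = list(
        inputs = c("modules.tsv", "pathways.gmt", "autophagy_genes.txt"),
        outputs = c("enrichment.tsv", "selected_module.txt",
                    "venn_counts.json")),
    prognosis = list(
        inputs = c("mrna_expr.tsv", "lnc_counts.tsv", "pheno.tsv",
                   "survival.tsv", "modules.tsv", "selected_module.txt"),
        outputs = c("univariate_cox.tsv", "risk_model.json",
                    "risk_scores.tsv", "km_logrank.json", "forest.tsv",
                    "td_auc.tsv")))

simConfigFrom <- function(cfg) do.call(simConfig, cfg$sim)

wtsv <- function(df, path) write.table(df, path, sep = "\t", quote = FALSE,
                                       row.names = FALSE)

runStage <- function(stage, dir, cfg) {
    fp <- function(f) file.path(dir, f)
    switch(stage,
    simulate = {
        sim <- simulateCrosstalkStudy(simConfigFrom(cfg))
        writeSimulation(sim, dir)
    },
    preprocess = {
        pheno <- readPheno(fp("pheno.tsv"))
        se <- readCountsTsv(fp("mrna_counts.tsv"), pheno)
        lens <- readGeneLengths(fp("gene_lengths.tsv"))
        se <- cpmFilter(se, cfg$preprocess$cpm_threshold,
                        cfg$preprocess$cpm_frac)
        expr <- tpmNormalize(se, lens, log = TRUE)
        wtsv(data.frame(gene = rownames(expr), expr, check.names = FALSE),
             fp("mrna_expr.tsv"))
    },
    delnc = {
        pheno <- readPheno(fp("pheno.tsv"))
        se <- readCountsTsv(fp("lnc_counts.tsv"), pheno)
        de <- deLncRNA(se, cfg$de$p, cfg$de$lfc)
        wtsv(de, fp("de_lncrna.tsv"))
    },
    pagi = {
        pheno <- readPheno(fp("pheno.tsv"))
        expr <- as.matrix(read.delim(fp("mrna_expr.tsv"), row.names = 1,
                                     check.names = FALSE))
        pc <- readPathwayCollection(fp("pathways.gmt"),
                                    fp("pathway_edges.tsv"))
        res <- pagiScore(expr, pheno$group[match(colnames(expr),
                                                 pheno$sample)],
                         pc, B = cfg$pagi$permutations, r = cfg$pagi$restart,
                         fdrCut = cfg$pagi$fdr, seed = cfg$sim$seed)
        wtsv(pathwayScores(res), fp("pathway_scores.tsv"))
        wtsv(geneInfluence(res), fp("gene_influence.tsv"))
    },
    crosstalk = {
        pc <- readPathwayCollection(fp("pathways.gmt"),
                                    fp("pathway_edges.tsv"))
        scores <- read.delim(fp("pathway_scores.tsv"))
        infl <- read.delim(fp("gene_influence.tsv"))
        aut <- readLines(fp("autophagy_genes.txt"))
        exprGenes <- read.delim(fp("mrna_expr.tsv"), row.names = 1,
                                check.names = FALSE, nrows = -1)
        res <- new("PagiResult", scores = scores, influence = infl,
                   params = list(fdrCut = cfg$pagi$fdr))
        res <- annotateAutophagy(res, pc, aut)
        sel <- selectFeatures(res, pc, rownames(exprGenes),
                              cfg$crosstalk$min_autophagy, cfg$pagi$fdr, aut)
        wtsv(res@scores[res@scores$pathway_id %in% sel@features, ],
             fp("feature_pathways.tsv"))
        writeLines(sel@featureMrnas, fp("feature_mrnas.txt"))
        wtsv(topGenesPerPathway(sel@features, pc, infl,
                                cfg$crosstalk$top_k),
             fp("pathway_gene_network.tsv"))
    },
    coexpr = {
        expr <- as.matrix(read.delim(fp("mrna_expr.tsv"), row.names = 1,
                                     check.names = FALSE))
        featGenes <- readLines(fp("feature_mrnas.txt"))
        de <- read.delim(fp("de_lncrna.tsv"))
        pheno <- readPheno(fp("pheno.tsv"))
        lnc <- readCountsTsv(fp("lnc_counts.tsv"), pheno)
        lncSig <- de$gene[de$significant]
        lncExpr <- if (length(lncSig)) {
            sf <- computeSizeFactors(lnc)
            log2(t(t(countsOf(lnc)[lncSig, , drop = FALSE]) / sf) + 1)
        } else NULL
        input <- rbind(expr[intersect(featGenes, rownames(expr)), ,
                            drop = FALSE],
                       lncExpr[, colnames(expr), drop = FALSE])
        ms <- coexpressionModules(input,
                                  minSize = cfg$coexpr$min_module_size,
                                  mergeHeight = cfg$coexpr$merge_height,
                                  r2Cut = cfg$coexpr$r2)
        asg <- moduleAssignment(ms)
        wtsv(data.frame(gene = names(asg),
                        type = ifelse(names(asg) %in% lncSig, "lncRNA",
                                      "mRNA"),
                        module = asg), fp("modules.tsv"))
        eg <- moduleEigengenes(ms)
        wtsv(data.frame(module = rownames(eg), eg, check.names = FALSE),
             fp("eigengenes.tsv"))
        scanOut <- ms@scan
        scanOut$chosen <- scanOut$beta == softThresholdBeta(ms)
        wtsv(scanOut, fp("soft_threshold_scan.tsv"))
    },
    enrich = {
        mod <- read.delim(fp("modules.tsv"))
        pc <- readPathwayCollection(fp("pathways.gmt"))
        aut <- readLines(fp("autophagy_genes.txt"))
        asg <- setNames(mod$module, mod$gene)
        bg <- mod$gene
        enr <- hypergeomEnrich(asg, pathwayGenes(pc), bg)
        wtsv(enr, fp("enrichment.tsv"))
        # reference disease pathway: the strongest-scoring enriched pathway
        adId <- enr$pathway[order(enr$p)][1]
        selm <- selectModule(asg, aut, pathwayGenes(pc, adId))
        writeLines(selm$module, fp("selected_module.txt"))
        jsonlite::write_json(selm$venn, fp("venn_counts.json"),
                             auto_unbox = TRUE, digits = NA)
    },
    prognosis = {
        expr <- as.matrix(read.delim(fp("mrna_expr.tsv"), row.names = 1,
                                     check.names = FALSE))
        pheno <- readPheno(fp("pheno.tsv"))
        lnc <- readCountsTsv(fp("lnc_counts.tsv"), pheno)
        sf <- computeSizeFactors(lnc)
        lncExpr <- log2(t(t(countsOf(lnc)) / sf) + 1)[, colnames(expr)]
        surv <- readSurvivalTsv(fp("survival.tsv"))
        mod <- read.delim(fp("modules.tsv"))
        chosen <- readLines(fp("selected_module.txt"))[1]
        genes <- mod$gene[mod$module == chosen]
        full <- rbind(expr, lncExpr)
        genes <- intersect(genes, rownames(full))
        x <- full[genes, surv$sample, drop = FALSE]
        rm <- buildRiskModel(x, surv, uniP = cfg$cox$uni_p,
                             relaxIfEmpty = TRUE)
        wtsv(rm$univariate, fp("univariate_cox.tsv"))
        jsonlite::write_json(
            list(genes = modelGenes(rm$model),
                 coefficients = as.numeric(rm$model@coefficients),
                 aic = rm$model@aic, cutoff = modelCutoff(rm$model)),
            fp("risk_model.json"), auto_unbox = TRUE, digits = NA,
            pretty = TRUE)
        split <- riskSplit(rm$model, x)
        split$dataset <- surv$dataset[match(split$sample, surv$sample)]
        wtsv(split, fp("risk_scores.tsv"))
        train <- rm$train
        kmr <- kmLogrank(train, split$risk[match(train$sample,
                                                 split$sample)])
        jsonlite::write_json(list(chisq = kmr$chisq, p = kmr$p),
                             fp("km_logrank.json"), auto_unbox = TRUE,
                             digits = NA)
        sc <- split$score[match(surv$sample, split$sample)]
        wtsv(independentPrognostic(surv, sc), fp("forest.tsv"))
        td <- timeDependentAUC(surv, sc, cfg$cox$times)
        mi <- multiIndexAUC(surv, sc, cfg$cox$ref_time)
        wtsv(td, fp("td_auc.tsv"))
        wtsv(mi, fp("multi_index_auc.tsv"))
    },
    stop("unknown stage: ", stage))
    invisible(NULL)
}

#' Run the full pipeline
#'
#' Executes simulate, preprocess, delnc, pagi, crosstalk, coexpr, enrich
#' and prognosis in order against a working directory, checking each
#' stage's declared inputs before running it, and records a manifest
#' (configuration snapshot, seed, per-file MD5 hashes, warnings,
#' timings) as `manifest.json`. Re-running with the same configuration
#' and seed reproduces identical hashes.
#'
#' @param dir working/output directory.
#' @param config configuration list from [pipelineConfig()].
#' @param seed optional integer overriding `config$sim$seed`.
#' @param from start at this stage, reusing upstream files already in
#'   `dir`; a missing input raises an error naming the stage that
#'   produces it.
#' @return the manifest, invisibly.
#' @export
runAll <- function(dir, config = pipelineConfig(), seed = NULL,
                   from = NULL) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    if (!is.null(seed)) config$sim$seed <- as.integer(seed)
    stages <- pipelineStages()
    order <- names(stages)
    start <- if (is.null(from)) 1L else match(from, order)
    if (is.na(start)) stop("unknown stage: ", from)
    producer <- unlist(lapply(order, function(s)
        setNames(rep(s, length(stages[[s]]$outputs)), stages[[s]]$outputs)))
    manifest <- list(config = config, seed = config$sim$seed,
                     stages = list())
    for (s in order[start:length(order)]) {
        miss <- stages[[s]]$inputs[!file.exists(file.path(
            dir, stages[[s]]$inputs))]
        if (length(miss))
            stop("stage '", s, "' is missing input(s) ",
                 paste(miss, collapse = ", "), " produced by stage '",
                 paste(unique(producer[miss]), collapse = ", "), "'")
        warns <- character(0)
        tm <- system.time(withCallingHandlers(
            runStage(s, dir, config),
            warning = function(w) {
                warns <<- c(warns, conditionMessage(w))
                invokeRestart("muffleWarning")
            }))
        outs <- file.path(dir, stages[[s]]$outputs)
        manifest$stages[[s]] <- list(
            elapsed = unname(tm["elapsed"]),
            warnings = warns,
            outputs = as.list(tools::md5sum(outs[file.exists(outs)])))
    }
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(manifest)
}
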