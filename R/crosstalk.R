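#' Annotate pathway score records with autophagy-gene counts
#'
#' @param res a [PagiResult-class].
#' @param pc the [PathwayCollection-class] that was scored.
#' @param autophagyGenes character vector of autophagy gene symbols.
#' @return the `PagiResult` with an `autophagy_count` column added to its
#'   score table.
#' @export
annotateAutophagy <- function(res, pc, autophagyGenes) {
    stopifnot(is(res, "PagiResult"), is(pc, "PathwayCollection"))
    if (!length(autophagyGenes)) stop("empty autophagy gene list")
    cnt <- vapply(res@scores$pathway_id, function(id)
        length(intersect(pathwayGenes(pc, id), autophagyGenes)), integer(1))
    res@scores$autophagy_count <- as.integer(cnt)
    res
}

#' Select feature pathways and feature mRNAs (crosstalk genes)
#'
#' Candidate pathways are those below the FDR cut; feature pathways are
#' candidates containing at least `minAutophagy` autophagy genes (the
#' computable stand-in for annotation plus literature review). The
#' feature mRNAs — the crosstalk genes carried forward to coexpression
#' analysis — are the union of the feature pathways' members restricted
#' to the expression profile.
#'
#' @param res a [PagiResult-class], annotated by [annotateAutophagy()].
#' @param pc the scored [PathwayCollection-class].
#' @param exprGenes gene ids of the expression profile.
#' @param minAutophagy minimum autophagy-gene count (default 5).
#' @param fdrCut candidate threshold (default 0.01).
#' @param autophagyGenes the autophagy list, stored on the selection for
#'   downstream use.
#' @return a [FeatureSelection-class]. When no candidate passes the
#'   autophagy rule a warning is emitted and all candidates are kept.
#' @export
selectFeatures <- function(res, pc, exprGenes, minAutophagy = 5L,
                           fdrCut = 0.01, autophagyGenes = character(0)) {
    sc <- res@scores
    if (is.null(sc$autophagy_count))
        stop("run annotateAutophagy() first")
    cand <- sc$pathway_id[!is.na(sc$fdr) & sc$fdr < fdrCut]
    feat <- sc$pathway_id[sc$pathway_id %in% cand &
                          sc$autophagy_count >= minAutophagy]
    if (!length(feat) && length(cand)) {
        warning("no candidate pathway reaches ", minAutophagy,
                " autophagy genes; keeping all candidates")
        feat <- cand
    }
    mem <- unique(unlist(pc@genes[match(feat, pc@ids)]))
    new("FeatureSelection", candidates = cand, features = feat,
        featureMrnas = as.character(sort(intersect(mem, exprGenes))),
        autophagyGenes = as.character(autophagyGenes))
}

#' Top GDS genes of each feature pathway
#'
#' For a pathway-gene network export: the `k` member genes with the
#' highest GDS per feature pathway (ties broken by gene id; pathways
#' smaller than `k` contribute all members).
#'
#' @param features pathway ids (e.g. `featurePathways(selection)`).
#' @param pc the [PathwayCollection-class].
#' @param influence the influence table from a [PagiResult-class]
#'   (see [geneInfluence()]).
#' @param k genes per pathway (default 20).
#' @return data.frame `pathway`, `gene`, `gds` — a bipartite edge table.
#' @export
topGenesPerPathway <- function(features, pc, influence, k = 20L) {
    do.call(rbind, lapply(features, function(id) {
        g <- pathwayGenes(pc, id)
        gds <- influence$gds[match(g, influence$gene)]
        gds[is.na(gds)] <- 0
        ord <- order(-gds, g)
        top <- head(ord, k)
        data.frame(pathway = id, gene = g[top], gds = gds[top],
                   stringsAsFactors = FALSE)
    }))
}
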