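#' @import methods
#' @importFrom stats cor cutree dist hclust median p.adjust pchisq phyper
#'   pnorm prcomp pt quantile rbinom rexp rnorm rpois runif sd setNames var
#'   as.dist lm coef qnorm
#' @importFrom utils head read.delim write.table combn
NULL

#' Simulation configuration for a planted crosstalk study
#'
#' Holds every parameter of the synthetic-data generator: the gene universe,
#' the pathway collection with crosstalk (shared membership between
#' neighbouring pathways), planted dysregulation, planted coexpression
#' modules, planted differential lncRNAs, and the proportional-hazards
#' survival model driven by two planted prognostic genes.
#'
#' Counts are generated on the log2 scale (baseline + planted effects +
#' module latent factors + gene-level biological noise), exponentiated and
#' Poisson-rounded, giving negative-binomial-like marginals whose
#' overdispersion is controlled by `nbDispersion`.
#'
#' @slot nGenes,nLnc number of mRNAs / lncRNAs in the universe.
#' @slot nPathways number of pathways; `pathwaySizeRange` bounds their sizes.
#' @slot crosstalkOverlap fraction of each pathway's genes shared with its
#'   neighbour pathway (crosstalk realised as shared membership).
#' @slot nDysregulated number of pathways carrying a planted case-group
#'   mean shift of `effectDelta` log2 units on `affectedFraction` of their
#'   members.
#' @slot nCase,nControl,nBatches sample-group sizes and number of
#'   (effect-free by default) sequencing batches.
#' @slot nbDispersion negative-binomial dispersion of the counts.
#' @slot nModules,moduleSize,moduleFactorSd planted coexpression modules:
#'   each module adds `loading * factor` on the log2 scale with
#'   `loading ~ |N(0, moduleFactorSd)|` and a standard-normal per-sample
#'   latent factor.
#' @slot lncDeFraction,lncDeLfc fraction of lncRNAs planted as
#'   differentially expressed and their log2-fold-change magnitude.
#' @slot prognosticCoefs the two planted Cox log-hazard coefficients
#'   (defaults -1.13 and -1.41, i.e. protective genes).
#' @slot baselineHazard,censorHorizon exponential baseline event rate
#'   (events/year) and the upper bound of the uniform censoring time.
#' @slot batchEffectSd optional additive per-batch log2 offset (0 = no
#'   batch effect; non-zero only for robustness experiments).
#' @slot seed integer seed; identical configurations reproduce
#'   byte-identical outputs.
#' @export
setClass("SimConfig", representation(
    nGenes = "integer", nLnc = "integer",
    nPathways = "integer", pathwaySizeRange = "integer",
    crosstalkOverlap = "numeric", nDysregulated = "integer",
    effectDelta = "numeric", affectedFraction = "numeric",
    nCase = "integer", nControl = "integer", nBatches = "integer",
    nbDispersion = "numeric",
    nModules = "integer", moduleSize = "integer", moduleFactorSd = "numeric",
    lncDeFraction = "numeric", lncDeLfc = "numeric",
    prognosticCoefs = "numeric", baselineHazard = "numeric",
    censorHorizon = "numeric", batchEffectSd = "numeric",
    seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    fr <- c(crosstalkOverlap = object@crosstalkOverlap,
            affectedFraction = object@affectedFraction,
            lncDeFraction = object@lncDeFraction)
    bad <- fr < 0 | fr > 1
    if (any(bad))
        msg <- c(msg, paste0("fractions must lie in [0,1]: ",
                             paste(names(fr)[bad], collapse = ", ")))
    if (length(object@pathwaySizeRange) != 2L ||
        object@pathwaySizeRange[1] > object@pathwaySizeRange[2])
        msg <- c(msg, "pathwaySizeRange must be (min, max) with min <= max")
    if (object@pathwaySizeRange[2] > object@nGenes)
        msg <- c(msg, "pathwaySizeRange max exceeds nGenes")
    if (object@nDysregulated > object@nPathways)
        msg <- c(msg, "nDysregulated exceeds nPathways")
    if (length(object@prognosticCoefs) != 2L)
        msg <- c(msg, "prognosticCoefs must have length 2")
    if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
    if (object@censorHorizon < 0) msg <- c(msg, "censorHorizon must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class Constructor with the default study
#'   conditions: a 2000-mRNA universe carrying 20 pathways of 20-30 genes
#'   with 20% crosstalk overlap, 4 dysregulated pathways shifted by 1 log2
#'   unit on half their members, 155 case and 86 control samples over 9
#'   batches, 3 planted modules of 120 genes, 30% of 200 lncRNAs planted
#'   as DE at |log2FC| = 1, and protective prognostic coefficients
#'   (-1.13, -1.41).
#' @param nGenes,nLnc,nPathways,pathwaySizeRange,crosstalkOverlap,nDysregulated,effectDelta,affectedFraction,nCase,nControl,nBatches,nbDispersion,nModules,moduleSize,moduleFactorSd,lncDeFraction,lncDeLfc,prognosticCoefs,baselineHazard,censorHorizon,batchEffectSd,seed see slot documentation.
#' @export
simConfig <- function(nGenes = 2000L, nLnc = 200L,
                      nPathways = 20L, pathwaySizeRange = c(20L, 30L),
                      crosstalkOverlap = 0.2, nDysregulated = 4L,
                      effectDelta = 1.0, affectedFraction = 0.5,
                      nCase = 155L, nControl = 86L, nBatches = 9L,
                      nbDispersion = 0.1,
                      nModules = 3L, moduleSize = 120L, moduleFactorSd = 3.0,
                      lncDeFraction = 0.3, lncDeLfc = 1.0,
                      prognosticCoefs = c(-1.13, -1.41),
                      baselineHazard = 0.2, censorHorizon = 10,
                      batchEffectSd = 0, seed = 1L) {
    new("SimConfig",
        nGenes = as.integer(nGenes), nLnc = as.integer(nLnc),
        nPathways = as.integer(nPathways),
        pathwaySizeRange = as.integer(pathwaySizeRange),
        crosstalkOverlap = crosstalkOverlap,
        nDysregulated = as.integer(nDysregulated),
        effectDelta = effectDelta, affectedFraction = affectedFraction,
        nCase = as.integer(nCase), nControl = as.integer(nControl),
        nBatches = as.integer(nBatches), nbDispersion = nbDispersion,
        nModules = as.integer(nModules), moduleSize = as.integer(moduleSize),
        moduleFactorSd = moduleFactorSd, lncDeFraction = lncDeFraction,
        lncDeLfc = lncDeLfc, prognosticCoefs = prognosticCoefs,
        baselineHazard = baselineHazard, censorHorizon = censorHorizon,
        batchEffectSd = batchEffectSd, seed = as.integer(seed))
}

#' Collection of pathway gene sets with within-pathway interaction edges
#'
#' @slot ids,pathwayNames pathway identifiers and display names.
#' @slot genes named list; member gene ids per pathway.
#' @slot edges data.frame with columns `pathway`, `from`, `to`
#'   (undirected within-pathway gene-gene edges).
#' @export
setClass("PathwayCollection", representation(
    ids = "character", pathwayNames = "character",
    genes = "list", edges = "data.frame"))

setValidity("PathwayCollection", function(object) {
    msg <- character()
    if (anyDuplicated(object@ids)) msg <- c(msg, "duplicate pathway ids")
    if (length(object@ids) != length(object@genes) ||
        length(object@ids) != length(object@pathwayNames))
        msg <- c(msg, "ids, pathwayNames and genes lengths differ")
    if (nrow(object@edges)) {
        for (col in c("pathway", "from", "to"))
            if (is.null(object@edges[[col]]))
                msg <- c(msg, paste("edges lacks column", col))
        if (!length(msg)) {
            memb <- Map(function(p, a, b) {
                g <- object@genes[[match(p, object@ids)]]
                all(c(a, b) %in% g)
            }, object@edges$pathway, object@edges$from, object@edges$to)
            if (!all(unlist(memb)))
                msg <- c(msg, "edge endpoint outside its pathway's gene set")
        }
    }
    if (length(msg)) msg else TRUE
})

#' @rdname PathwayCollection-class
#' @param ids,pathwayNames,genes,edges see slots.
#' @export
PathwayCollection <- function(ids, genes, pathwayNames = ids,
                              edges = data.frame(pathway = character(),
                                                 from = character(),
                                                 to = character())) {
    new("PathwayCollection", ids = as.character(ids),
        pathwayNames = as.character(pathwayNames),
        genes = as.list(genes), edges = edges)
}

#' Global gene-gene network merged from pathway graphs
#'
#' Nodes are the union of all pathway members; edges the union of
#' within-pathway edges (duplicates collapsed). Genes shared by two or
#' more pathways connect the pathway subgraphs, so crosstalk is realised
#' through shared nodes. `transition` is the column-normalised adjacency
#' used by the random walk with restart; zero-degree columns are left at
#' zero.
#'
#' @slot nodes ordered gene ids.
#' @slot adjacency symmetric sparse 0/1 matrix with zero diagonal.
#' @slot transition column-stochastic (on non-empty columns) sparse matrix.
#' @export
setClass("GlobalNetwork", representation(
    nodes = "character", adjacency = "Matrix", transition = "Matrix"))

setValidity("GlobalNetwork", function(object) {
    msg <- character()
    A <- object@adjacency
    if (nrow(A) != length(object@nodes))
        msg <- c(msg, "adjacency dimension does not match nodes")
    if (!Matrix::isSymmetric(A)) msg <- c(msg, "adjacency not symmetric")
    if (any(Matrix::diag(A) != 0)) msg <- c(msg, "adjacency diagonal not zero")
    cs <- Matrix::colSums(object@transition)
    if (any(abs(cs[cs > 0] - 1) > 1e-8))
        msg <- c(msg, "non-empty transition columns must sum to 1")
    if (length(msg)) msg else TRUE
})

#' Result of PAGI pathway scoring
#'
#' @slot scores per-pathway records: running-sum score, peak position,
#'   gene percentage before the peak, leading-edge signal, permutation p,
#'   BH FDR and (after annotation) autophagy-gene count.
#' @slot influence per-gene table: signed Welch t, |t|, stationary RWR
#'   probability, GDS and ranking weight.
#' @slot params scoring parameters (restart probability, permutations,
#'   seed, ...).
#' @export
setClass("PagiResult", representation(
    scores = "data.frame", influence = "data.frame", params = "list"))

#' Feature-pathway / feature-mRNA selection
#'
#' @slot candidates pathway ids passing the FDR cut.
#' @slot features candidate pathways passing the autophagy-content rule.
#' @slot featureMrnas union of feature-pathway members present in the
#'   expression profile (the crosstalk genes).
#' @slot autophagyGenes the autophagy annotation list used.
#' @export
setClass("FeatureSelection", representation(
    candidates = "character", features = "character",
    featureMrnas = "character", autophagyGenes = "character"))

setValidity("FeatureSelection", function(object) {
    if (!all(object@features %in% object@candidates))
        "features must be a subset of candidates" else TRUE
})

#' Coexpression module assignment
#'
#' @slot assignment named character vector gene -> module label
#'   ("grey" = unassigned).
#' @slot eigengenes modules x samples matrix of module eigengenes (first
#'   principal component of the standardised module submatrix).
#' @slot beta chosen soft-threshold power.
#' @slot scan the soft-threshold scan table.
#' @export
setClass("ModuleSet", representation(
    assignment = "character", eigengenes = "matrix",
    beta = "numeric", scan = "data.frame"))

#' Cox risk-score model
#'
#' riskScore(x) = sum_k coef(k) * x(k) over the signature genes; samples
#' with score strictly greater than the training-median cutoff are called
#' high-risk.
#'
#' @slot genes signature gene ids (ordered).
#' @slot coefficients Cox log-hazard coefficients.
#' @slot aic partial-likelihood AIC of the final model.
#' @slot cutoff training-median risk score.
#' @slot center,scale per-gene training-set standardisation applied to
#'   expression before scoring.
#' @export
setClass("RiskModel", representation(
    genes = "character", coefficients = "numeric", aic = "numeric",
    cutoff = "numeric", center = "numeric", scale = "numeric"))

setValidity("RiskModel", function(object) {
    if (length(object@genes) != length(object@coefficients))
        "genes and coefficients lengths differ" else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "mRNAs,", object@nLnc, "lncRNAs,",
        object@nPathways, "pathways (", object@nDysregulated,
        "dysregulated, delta =", object@effectDelta, ")\n")
    cat("  samples:", object@nCase, "case /", object@nControl, "control;",
        object@nModules, "modules x", object@moduleSize, "genes; seed",
        object@seed, "\n")
})

setMethod("show", "PathwayCollection", function(object) {
    cat("PathwayCollection with", length(object@ids), "pathways,",
        length(unique(unlist(object@genes))), "distinct genes,",
        nrow(object@edges), "within-pathway edges\n")
})

setMethod("show", "GlobalNetwork", function(object) {
    cat("GlobalNetwork:", length(object@nodes), "nodes,",
        Matrix::nnzero(object@adjacency) / 2, "edges\n")
})

setMethod("show", "PagiResult", function(object) {
    ns <- sum(object@scores$fdr < object@params$fdrCut)
    cat("PagiResult:", nrow(object@scores), "pathways scored (",
        object@params$permutations, "permutations ), ", ns,
        "significant at FDR <", object@params$fdrCut, "\n")
})

setMethod("show", "ModuleSet", function(object) {
    tab <- table(object@assignment[object@assignment != "grey"])
    cat("ModuleSet: beta =", object@beta, ";", length(tab), "modules (",
        paste(names(tab), tab, sep = ":", collapse = ", "), ");",
        sum(object@assignment == "grey"), "unassigned\n")
})

setMethod("show", "RiskModel", function(object) {
    cat("RiskModel:",
        paste(sprintf("%s (%.3f)", object@genes, object@coefficients),
              collapse = " + "),
        "\n  AIC =", round(object@aic, 2),
        "; training-median cutoff =", signif(object@cutoff, 4), "\n")
})

## ---- accessors ----------------------------------------------------------

#' @rdname PathwayCollection-class
#' @param x a `PathwayCollection`.
#' @export
pathwayIds <- function(x) x@ids

#' @rdname PathwayCollection-class
#' @param pathway optional single pathway id.
#' @export
pathwayGenes <- function(x, pathway = NULL) {
    if (is.null(pathway)) setNames(x@genes, x@ids)
    else x@genes[[match(pathway, x@ids)]]
}

#' @rdname PathwayCollection-class
#' @export
pathwayEdges <- function(x) x@edges

#' @rdname GlobalNetwork-class
#' @param x a `GlobalNetwork`.
#' @export
networkNodes <- function(x) x@nodes

#' @rdname PagiResult-class
#' @param x a `PagiResult`.
#' @export
pathwayScores <- function(x) x@scores

#' @rdname PagiResult-class
#' @export
geneInfluence <- function(x) x@influence

#' @rdname ModuleSet-class
#' @param x a `ModuleSet`.
#' @export
moduleAssignment <- function(x) x@assignment

#' @rdname ModuleSet-class
#' @export
moduleEigengenes <- function(x) x@eigengenes

#' @rdname ModuleSet-class
#' @export
softThresholdBeta <- function(x) x@beta

#' @rdname RiskModel-class
#' @param x a `RiskModel`.
#' @export
modelGenes <- function(x) x@genes

#' @rdname RiskModel-class
#' @export
modelCoefficients <- function(x) setNames(x@coefficients, x@genes)

#' @rdname RiskModel-class
#' @export
modelCutoff <- function(x) x@cutoff

#' @rdname FeatureSelection-class
#' @param x a `FeatureSelection`.
#' @export
featureMrnas <- function(x) x@featureMrnas

#' @rdname FeatureSelection-class
#' @export
featurePathways <- function(x) x@features
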