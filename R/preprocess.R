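#' Filter lowly expressed genes by counts per million
#'
#' Removes genes whose CPM falls below `threshold` in at least `frac` of
#' the samples (so a gene below threshold in exactly half the samples is
#' removed at the defaults). CPM is `count / (library size / 1e6)`.
#'
#' @param se `SummarizedExperiment` with a `counts` assay (or a matrix).
#' @param threshold CPM threshold (default 1).
#' @param frac removal fraction (default 0.5); a gene is kept only when it
#'   reaches the threshold in strictly more than `1 - frac` of samples.
#' @return the input restricted to the retained genes.
#' @export
cpmFilter <- function(se, threshold = 1, frac = 0.5) {
    m <- countsOf(se)
    if (ncol(m) < 1L) stop("no samples")
    lib <- colSums(m)
    if (any(lib <= 0)) stop("library sizes must be positive")
    cpm <- t(t(m) / lib) * 1e6
    keep <- rowMeans(cpm < threshold) < frac
    if (!any(keep)) stop("CPM filter removed every gene")
    if (is(se, "SummarizedExperiment")) se[keep, ] else m[keep, , drop = FALSE]
}

#' TPM normalisation
#'
#' Length-then-library scaling: `rate = count / length`,
#' `TPM = 1e6 * rate / sum(rate)` per sample, so every column sums to one
#' million. With `log = TRUE` values become `log2(TPM + 1)`.
#'
#' @param se counts (`SummarizedExperiment` or matrix).
#' @param lengths named vector of gene lengths in bp; defaults to the
#'   `length` column of `rowData(se)`.
#' @param log return `log2(TPM + 1)` instead of TPM.
#' @return numeric matrix, genes x samples.
#' @export
tpmNormalize <- function(se, lengths = NULL, log = FALSE) {
    m <- countsOf(se)
    if (is.null(lengths) && is(se, "SummarizedExperiment"))
        lengths <- setNames(SummarizedExperiment::rowData(se)$length,
                            rownames(se))
    miss <- setdiff(rownames(m), names(lengths))
    if (length(miss))
        stop("missing gene lengths for: ",
             paste(head(miss, 5), collapse = ", "),
             if (length(miss) > 5) " ...")
    len <- lengths[rownames(m)]
    if (any(len <= 0)) stop("gene lengths must be positive")
    rate <- m / len
    tot <- colSums(rate)
    if (any(tot == 0)) stop("all-zero sample(s): ",
                            paste(colnames(m)[tot == 0], collapse = ", "))
    tpm <- t(t(rate) / tot) * 1e6
    if (log) log2(tpm + 1) else tpm
}

#' Median-of-ratios size factors
#'
#' Reference profile = per-gene geometric mean over samples, using only
#' genes with all-positive counts; a sample's size factor is the median
#' ratio of its counts to the reference.
#'
#' @param m counts matrix (or `SummarizedExperiment`).
#' @return named positive numeric vector, one per sample.
#' @export
computeSizeFactors <- function(m) {
    m <- countsOf(m)
    pos <- rowSums(m <= 0) == 0
    if (!any(pos))
        stop("no gene with all-positive counts; cannot form a reference")
    lg <- log(m[pos, , drop = FALSE])
    logref <- rowMeans(lg)
    # median taken on the log scale (geometric interpolation between the
    # two central ratios when the gene count is even)
    apply(lg, 2, function(x) exp(median(x - logref)))
}

#' Differential expression of lncRNAs
#'
#' A documented stand-in for a full negative-binomial DE fit: counts are
#' normalised by median-of-ratios size factors, transformed to
#' `log2(count / sizeFactor + 1)`, and each gene is tested case vs
#' control with a Welch two-sample t-test. A gene is called significant
#' when `p < pCut` and `|log2FC| > lfcCut` (defaults 0.05 and 0.5). No
#' multiple-testing correction is applied to the DE calls. Genes with
#' zero variance in both groups get `log2FC = 0`, `p = 1`.
#'
#' The batch label is not part of the test; a warning notes when more
#' than one batch is present.
#'
#' @param se lncRNA counts with `group` in `colData`.
#' @param pCut,lfcCut significance thresholds.
#' @return data.frame `gene`, `log2FC` (case minus control), `p`,
#'   `significant`; size factors attached as `attr(, "sizeFactors")`.
#' @export
deLncRNA <- function(se, pCut = 0.05, lfcCut = 0.5) {
    m <- countsOf(se)
    grp <- groupOf(se)
    case <- grp == "AD"
    if (sum(case) < 2L || sum(!case) < 2L)
        stop("need at least 2 samples per group")
    b <- SummarizedExperiment::colData(se)$batch
    if (!is.null(b) && length(unique(b)) > 1L)
        warning("multiple batch labels present; the DE test has no batch term")
    sf <- computeSizeFactors(m)
    y <- log2(t(t(m) / sf) + 1)
    tt <- rowWelchT(y, case)
    res <- data.frame(gene = rownames(m),
                      log2FC = tt$mean_case - tt$mean_control,
                      p = tt$p, stringsAsFactors = FALSE)
    res$significant <- res$p < pCut & abs(res$log2FC) > lfcCut
    attr(res, "sizeFactors") <- sf
    res
}
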