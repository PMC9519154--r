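# Vectorised Welch two-sample t over matrix rows. Rows with zero pooled
# variance get t = 0, p = 1 (no evidence, by convention).
rowWelchT <- function(x, case) {
    stopifnot(is.logical(case), length(case) == ncol(x))
    n1 <- sum(case); n2 <- sum(!case)
    if (n1 < 2L || n2 < 2L)
        stop("need at least 2 samples per group for the Welch t-test")
    x1 <- x[, case, drop = FALSE]; x2 <- x[, !case, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                 1)
    p <- ifelse(se2 > 0, 2 * pt(-abs(t), df), 1)
    data.frame(gene = rownames(x), t = t, df = df, p = p,
               mean_case = m1, mean_control = m2, row.names = NULL,
               stringsAsFactors = FALSE)
}

# Seed scoped to a block of work; restores the caller's RNG state.
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# counts assay of a SummarizedExperiment (or a plain matrix passthrough)
countsOf <- function(x) {
    if (is(x, "SummarizedExperiment"))
        SummarizedExperiment::assay(x, "counts")
    else as.matrix(x)
}

groupOf <- function(x) {
    g <- SummarizedExperiment::colData(x)$group
    if (is.null(g)) stop("colData lacks a 'group' column")
    as.character(g)
}
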