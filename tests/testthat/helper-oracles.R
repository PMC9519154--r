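# Independent oracles used across the suite. Each reimplements the target
# quantity by the most literal route available (position-by-position walks,
# triple loops, direct linear solves, Newton on the partial likelihood) and
# never calls the code path it checks.

# running-sum enrichment score: walk the ranked list one position at a time
bruteForceScore <- function(ranked, members) {
    N <- nrow(ranked)
    inP <- ranked$gene %in% members
    Np <- sum(inP)
    if (Np == 0L || Np == N) return(NULL)
    NR <- sum(ranked$weight[inP])
    if (NR == 0) return(NULL)
    best <- 0; bestDev <- 0; bestI <- NA_integer_
    hit <- 0; miss <- 0
    for (i in seq_len(N)) {
        if (inP[i]) hit <- hit + ranked$weight[i] / NR
        else miss <- miss + 1 / (N - Np)
        dev <- hit - miss
        if (abs(dev) > best) { best <- abs(dev); bestDev <- dev; bestI <- i }
    }
    list(score = bestDev, peak_index = bestI)
}

# topological overlap by explicit triple loop
tomOracle <- function(a) {
    n <- nrow(a)
    k <- rowSums(a)
    out <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        num <- a[i, j]
        for (u in seq_len(n)) num <- num + a[i, u] * a[u, j]
        out[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
    }
    out
}

# stationary RWR distribution by direct linear solve
rwrLinearSolve <- function(M, p0, r) {
    as.numeric(solve(diag(nrow(M)) - (1 - r) * as.matrix(M), r * p0))
}

# upper-tail hypergeometric by explicit combinatorial sum
hyperTailOracle <- function(k, K, N, n) {
    tot <- 0
    for (x in k:min(K, n))
        tot <- tot + choose(K, x) * choose(N - K, n - x)
    tot / choose(N, n)
}

# one-covariate Cox (Breslow ties) by Newton iteration on the score
coxNewtonOracle <- function(time, event, x, tol = 1e-12) {
    ord <- order(time)
    time <- time[ord]; event <- event[ord]; x <- x[ord]
    beta <- 0
    for (it in 1:100) {
        U <- 0; I <- 0
        for (i in which(event == 1)) {
            risk <- which(time >= time[i])
            w <- exp(beta * x[risk])
            xb <- sum(w * x[risk]) / sum(w)
            x2 <- sum(w * x[risk]^2) / sum(w)
            U <- U + x[i] - xb
            I <- I + x2 - xb^2
        }
        step <- U / I
        beta <- beta + step
        if (abs(step) < tol) break
    }
    beta
}

adjustedRand <- function(a, b) mclust::adjustedRandIndex(a, b)

# normalised log2 expression of a counts matrix (median-of-ratios)
normLog2 <- function(counts) {
    sf <- pagicross::computeSizeFactors(counts)
    log2(t(t(counts) / sf) + 1)
}

assayOf <- function(se) SummarizedExperiment::assay(se, "counts")
groupsOf <- function(se) SummarizedExperiment::colData(se)$group
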