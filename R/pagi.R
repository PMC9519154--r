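#' Build the global gene network from pathway graphs
#'
#' Node set = union of all pathway members; edge set = union of the
#' within-pathway edges with duplicates collapsed. A gene belonging to
#' several pathways carries its edges from each of them, so pathway
#' subgraphs are connected through shared (crosstalk) genes. The
#' transition matrix is the column-normalised adjacency; zero-degree
#' columns are left at zero.
#'
#' @param pc a [PathwayCollection-class].
#' @return a [GlobalNetwork-class].
#' @export
buildGlobalNetwork <- function(pc) {
    stopifnot(is(pc, "PathwayCollection"))
    if (!length(pc@ids)) stop("empty pathway collection")
    nodes <- sort(unique(unlist(pc@genes)))
    e <- pc@edges
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
    if (nrow(e)) {
        a <- pmin(e$from, e$to); b <- pmax(e$from, e$to)
        dup <- duplicated(paste(a, b))
        i <- match(a[!dup], nodes); j <- match(b[!dup], nodes)
        A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                                  dims = c(length(nodes), length(nodes)),
                                  dimnames = list(nodes, nodes))
    }
    deg <- Matrix::colSums(A)
    inv <- ifelse(deg > 0, 1 / deg, 0)
    M <- A %*% Matrix::Diagonal(x = inv)
    dimnames(M) <- dimnames(A)
    new("GlobalNetwork", nodes = nodes, adjacency = A, transition = M)
}

#' Per-gene differential-expression t-scores
#'
#' Welch two-sample t statistic, case (AD) versus control, per gene of
#' the expression matrix. Downstream stages use `|t|`; a gene with zero
#' variance in both groups gets t = 0.
#'
#' @param expr numeric matrix, genes x samples (normalised expression).
#' @param group per-sample labels; `"AD"` marks the case group.
#' @return named numeric vector of signed t statistics.
#' @export
tScores <- function(expr, group) {
    tt <- rowWelchT(as.matrix(expr), group == "AD")
    setNames(tt$t, rownames(expr))
}

#' Random walk with restart and the global dysregulated score
#'
#' Every profiled gene present in the network is a source node with
#' initial probability proportional to its `|t|`
#' (`P0_i = |t_i| / sum |t|`); the walk iterates
#' `P <- (1 - r) * M %*% P + r * P0` until the L1 change drops below
#' `tol`. The stationary vector is min-max normalised into the GDS, and
#' each gene's ranking weight is `|t|^(1 + GDS)` — differential
#' expression amplified by global network influence.
#'
#' @param net a [GlobalNetwork-class].
#' @param t named vector of (signed or absolute) t-scores; genes absent
#'   from the vector propagate nothing (t = 0).
#' @param r restart probability in (0,1); default 0.7.
#' @param tol,maxIter convergence control.
#' @param p0 `"tscore"` (default) seeds the walk by |t|; `"uniform"`
#'   spreads the initial mass evenly over the nodes.
#' @return data.frame with one row per network node: `gene`, `t`
#'   (absolute), `p0`, `p_inf`, `gds`, `weight`.
#' @export
rwrGDS <- function(net, t, r = 0.7, tol = 1e-10, maxIter = 1000L,
                   p0 = c("tscore", "uniform")) {
    stopifnot(is(net, "GlobalNetwork"), r > 0, r < 1)
    p0 <- match.arg(p0)
    nodes <- net@nodes
    tt <- abs(t)[nodes]
    tt[is.na(tt)] <- 0
    names(tt) <- nodes
    P0 <- if (p0 == "uniform") rep(1 / length(nodes), length(nodes)) else {
        if (sum(tt) == 0)
            stop("all t-scores are zero on the network; nothing to propagate")
        tt / sum(tt)
    }
    M <- net@transition
    P <- P0
    converged <- FALSE
    for (it in seq_len(maxIter)) {
        Pn <- as.numeric((1 - r) * (M %*% P)) + r * P0
        if (sum(abs(Pn - P)) < tol) { P <- Pn; converged <- TRUE; break }
        P <- Pn
    }
    if (!converged)
        warning("random walk did not converge in ", maxIter,
                " iterations; returning the last iterate")
    rng <- range(P)
    gds <- if (diff(rng) > 0) (P - rng[1]) / diff(rng) else rep(0, length(P))
    data.frame(gene = nodes, t = as.numeric(tt), p0 = P0, p_inf = P,
               gds = gds, weight = as.numeric(tt)^(1 + gds),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank the expression profile by network-weighted differential expression
#'
#' All profiled genes are sorted by `w = |t|^(1 + GDS)` in decreasing
#' order; genes outside the network have GDS = 0, hence `w = |t|`. Ties
#' are broken by gene id so the ranking is deterministic.
#'
#' @param t named signed t-score vector over the expression profile.
#' @param influence result of [rwrGDS()].
#' @return data.frame ordered by rank: `gene`, `t` (absolute), `gds`,
#'   `weight`.
#' @export
rankGenes <- function(t, influence) {
    gds <- influence$gds[match(names(t), influence$gene)]
    gds[is.na(gds)] <- 0
    w <- abs(t)^(1 + gds)
    ord <- order(-w, names(t))
    data.frame(gene = names(t)[ord], t = abs(t)[ord], gds = gds[ord],
               weight = w[ord], row.names = NULL, stringsAsFactors = FALSE)
}

#' Weighted running-sum score of one pathway
#'
#' GSEA-style statistic along the ranked list `L`: the weighted hit CDF
#' `P_hit(i) = sum of member weights up to i / total member weight` is
#' compared with the uniform miss CDF
#' `P_miss(i) = #non-members up to i / (N - N_P)`; the score is the
#' signed deviation at the position of maximum absolute deviation.
#' `genePct` is that peak position as a fraction of the list, and
#' `signal = tagPct * (1 - genePct) * N / (N - N_P)` is the
#' leading-edge signal intensity, with `tagPct` the fraction of members
#' at or before the peak.
#'
#' @param ranked output of [rankGenes()].
#' @param members character vector of pathway member genes.
#' @return one-row data.frame (`score`, `peak_index`, `gene_pct`,
#'   `tag_pct`, `signal`, `size`), or `NULL` with a warning when the
#'   pathway maps to none or all of the list, or its mapped weights are
#'   all zero.
#' @export
pathwayScore <- function(ranked, members) {
    inP <- ranked$gene %in% members
    N <- nrow(ranked); Np <- sum(inP)
    if (Np == 0L || Np == N) {
        warning("pathway maps to none or all of the ranked list; skipped")
        return(NULL)
    }
    NR <- sum(ranked$weight[inP])
    if (NR == 0) {
        warning("all mapped member weights are zero; pathway skipped")
        return(NULL)
    }
    hit <- cumsum(ifelse(inP, ranked$weight, 0)) / NR
    miss <- cumsum(!inP) / (N - Np)
    dev <- hit - miss
    iStar <- which.max(abs(dev))
    data.frame(score = dev[iStar], peak_index = iStar,
               gene_pct = iStar / N,
               tag_pct = sum(inP[seq_len(iStar)]) / Np,
               signal = (sum(inP[seq_len(iStar)]) / Np) *
                   (1 - iStar / N) * N / (N - Np),
               size = Np, stringsAsFactors = FALSE)
}

# score every pathway against one ranking; returns named score vector and
# (optionally) the full records
scoreAllPathways <- function(ranked, pc, records = FALSE) {
    out <- lapply(pc@ids, function(id)
        suppressWarnings(pathwayScore(ranked, pathwayGenes(pc, id))))
    names(out) <- pc@ids
    if (records) out else
        vapply(out, function(x) if (is.null(x)) NA_real_ else x$score,
               numeric(1))
}

#' PAGI pathway scoring with permutation FDR
#'
#' The full scoring stage: build the global network, compute t-scores
#' and RWR-based GDS, rank genes by `|t|^(1 + GDS)` and score every
#' pathway with the weighted running-sum statistic. Significance comes
#' from `B` phenotype permutations: group labels are shuffled, t-scores
#' and ranking weights recomputed, and every pathway re-scored. The GDS
#' is held fixed at its observed value during permutations unless
#' `permuteGds = TRUE` (full RWR recomputation per permutation, feasible
#' on small networks). The permutation p-value compares absolute scores,
#' `p = (1 + #{|s_b| >= |s_obs|}) / (B + 1)`, and is BH-adjusted across
#' pathways; a pathway is flagged when `fdr < fdrCut`.
#'
#' @param expr normalised expression matrix, genes x samples.
#' @param group per-sample labels (`"AD"` = case).
#' @param pc a [PathwayCollection-class].
#' @param B number of permutations (default 200).
#' @param r restart probability (default 0.7).
#' @param fdrCut significance cut on the BH-adjusted permutation p
#'   (default 0.01).
#' @param seed integer seed for the permutations.
#' @param permuteGds recompute the random walk inside each permutation.
#' @param p0 initial-probability mode passed to [rwrGDS()].
#' @return a [PagiResult-class].
#' @export
pagiScore <- function(expr, group, pc, B = 200L, r = 0.7, fdrCut = 0.01,
                      seed = 1L, permuteGds = FALSE,
                      p0 = c("tscore", "uniform")) {
    p0 <- match.arg(p0)
    expr <- as.matrix(expr)
    if (B < 10L) stop("need at least 10 permutations")
    if (1 / (B + 1) > fdrCut)
        warning("B = ", B, " permutations cannot reach fdr < ", fdrCut,
                "; smallest attainable permutation p is ",
                signif(1 / (B + 1), 3))
    net <- buildGlobalNetwork(pc)
    tObs <- tScores(expr, group)
    infl <- rwrGDS(net, tObs, r = r, p0 = p0)
    ranked <- rankGenes(tObs, infl)
    obsRec <- scoreAllPathways(ranked, pc, records = TRUE)
    obs <- vapply(obsRec, function(x) if (is.null(x)) NA_real_ else x$score,
                  numeric(1))

    gdsLookup <- setNames(infl$gds, infl$gene)
    gdsAll <- gdsLookup[rownames(expr)]
    gdsAll[is.na(gdsAll)] <- 0
    case <- group == "AD"
    perm <- withSeed(seed + 7919L, {
        vapply(seq_len(B), function(b) {
            pg <- sample(case)
            tb <- abs(rowWelchT(expr, pg)$t)
            if (permuteGds) {
                ib <- rwrGDS(net, setNames(tb, rownames(expr)), r = r, p0 = p0)
                gb <- setNames(ib$gds, ib$gene)[rownames(expr)]
                gb[is.na(gb)] <- 0
            } else gb <- gdsAll
            wb <- tb^(1 + gb)
            ord <- order(-wb, rownames(expr))
            rb <- data.frame(gene = rownames(expr)[ord], weight = wb[ord],
                             stringsAsFactors = FALSE)
            scoreAllPathways(rb, pc)
        }, numeric(length(pc@ids)))
    })
    permAbs <- abs(perm)
    pPerm <- vapply(seq_along(obs), function(i) {
        if (is.na(obs[i])) return(NA_real_)
        (1 + sum(permAbs[i, ] >= abs(obs[i]), na.rm = TRUE)) / (B + 1)
    }, numeric(1))
    fdr <- p.adjust(pPerm, method = "BH")
    scores <- data.frame(
        pathway_id = pc@ids,
        name = pc@pathwayNames,
        size = vapply(obsRec, function(x) if (is.null(x)) 0L else
            as.integer(x$size), integer(1)),
        score = obs,
        peak_index = vapply(obsRec, function(x) if (is.null(x)) NA_integer_
            else as.integer(x$peak_index), integer(1)),
        gene_pct = vapply(obsRec, function(x) if (is.null(x)) NA_real_
            else x$gene_pct, numeric(1)),
        signal = vapply(obsRec, function(x) if (is.null(x)) NA_real_
            else x$signal, numeric(1)),
        perm_p = pPerm, fdr = fdr,
        significant = !is.na(fdr) & fdr < fdrCut,
        row.names = NULL, stringsAsFactors = FALSE)
    new("PagiResult", scores = scores, influence = infl,
        params = list(restart = r, permutations = as.integer(B),
                      fdrCut = fdrCut, seed = as.integer(seed),
                      permuteGds = permuteGds, p0 = p0))
}
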