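#' Soft-threshold scan for a scale-free coexpression network
#'
#' For each power `beta` in `betas` the unsigned adjacency
#' `a_ij = |cor(x_i, x_j)|^beta` (zero diagonal) is formed and the
#' scale-free fit index computed: connectivities `k_i = sum_j a_ij` are
#' binned into 10 equal-width bins and `log10(freq)` regressed on
#' `log10(mean k)` over non-empty bins; the R-squared is sign-flipped
#' when the slope is positive. Powers are eligible only while the
#' thresholded network keeps a mean connectivity of at least
#' `2 * ln(n)` — below that the network fragments and an apparently
#' good scale-free fit merely describes dust. The chosen power is the
#' eligible one with the highest mean connectivity among those whose
#' signed R-squared exceeds `r2Cut` (connectivity decreases in beta, so
#' this is the smallest qualifying power); when none qualifies the
#' best-fitting eligible power is taken with a warning.
#'
#' @param expr numeric matrix, genes x samples. Constant genes are
#'   dropped with a warning before correlation.
#' @param betas candidate powers (default 1:20).
#' @param r2Cut fit threshold (default 0.85).
#' @return list: `scan` (data.frame `beta`, `signed_r2`,
#'   `mean_connectivity`), `beta` (chosen power), `genes` (genes used).
#' @export
softThresholdScan <- function(expr, betas = 1:20, r2Cut = 0.85) {
    expr <- as.matrix(expr)
    if (nrow(expr) < 3L || ncol(expr) < 4L)
        stop("need at least 3 genes and 4 samples")
    v <- apply(expr, 1, var)
    if (any(v == 0)) {
        warning(sum(v == 0), " constant gene(s) excluded from the scan")
        expr <- expr[v > 0, , drop = FALSE]
    }
    S <- abs(cor(t(expr)))
    diag(S) <- 0
    scan <- do.call(rbind, lapply(betas, function(b) {
        k <- rowSums(S^b)
        data.frame(beta = b, signed_r2 = scaleFreeR2(k),
                   mean_connectivity = mean(k))
    }))
    elig <- scan$mean_connectivity >= 2 * log(nrow(expr))
    if (!any(elig)) elig[1] <- TRUE
    ok <- elig & scan$signed_r2 > r2Cut
    beta <- if (any(ok)) scan$beta[ok][which.max(scan$mean_connectivity[ok])]
    else {
        warning("no power reaches signed R^2 > ", r2Cut,
                " at workable connectivity; using the best-fitting ",
                "eligible power")
        scan$beta[elig][which.max(scan$signed_r2[elig])]
    }
    list(scan = scan, beta = beta, genes = rownames(expr))
}

# scale-free topology fit: signed R^2 of log10(freq) ~ log10(mean k) over
# 10 equal-width connectivity bins
scaleFreeR2 <- function(k, nBins = 10L) {
    br <- seq(min(k), max(k), length.out = nBins + 1L)
    if (br[1] == br[nBins + 1L]) return(0)
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    freq <- tabulate(bin, nbins = nBins)
    mk <- vapply(seq_len(nBins), function(i)
        if (freq[i]) mean(k[as.integer(bin) == i]) else NA_real_, numeric(1))
    use <- freq > 0 & mk > 0
    if (sum(use) < 3L) return(0)
    fit <- lm(log10(freq[use]) ~ log10(mk[use]))
    r2 <- summary(fit)$r.squared
    if (coef(fit)[2] > 0) -r2 else r2
}

#' Unsigned soft-threshold adjacency
#'
#' @param expr genes x samples matrix.
#' @param beta soft-threshold power.
#' @return symmetric adjacency with zero diagonal, entries in `[0, 1]`.
#' @export
adjacencyMatrix <- function(expr, beta) {
    a <- abs(cor(t(as.matrix(expr))))^beta
    diag(a) <- 0
    a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, and 1 on the diagonal; the clustering dissimilarity is
#' `1 - TOM`. Shared neighbourhood thus reinforces direct adjacency.
#'
#' @param a symmetric adjacency, zero diagonal, entries in `[0, 1]`.
#' @return the TOM (same dimension as `a`).
#' @export
tomMatrix <- function(a) {
    a <- as.matrix(a)
    stopifnot(isSymmetric(unname(a)), all(diag(a) == 0),
              all(a >= 0), all(a <= 1))
    k <- rowSums(a)
    num <- a %*% a + a
    den <- outer(k, k, pmin) + 1 - a
    tom <- num / den
    diag(tom) <- 1
    tom
}

#' Detect coexpression modules by adaptive static tree cut
#'
#' Average-linkage hierarchical clustering of the dissimilarity is cut
#' at a height starting at 0.99 of the top merge and descending in 2%
#' steps. A cluster of at least `minSize` genes whose membership is
#' identical across consecutive steps is *stable* — a genuine module
#' core occupies a height range free of merges, whereas noise clusters
#' shed members at almost every step and never stabilise. The descent
#' runs until no cluster of `minSize` genes remains; the maximal
#' disjoint stable clusters become module cores, and each core is then
#' climbed to its maximal dendrogram branch containing no other core,
#' so loosely attached members joining the branch below the
#' inter-module merge are included. Everything else is left unassigned
#' (`"grey"`). This deterministic cut replaces the dynamic tree cut
#' heuristics; see the vignette for the rationale and consequences.
#'
#' @param d square symmetric dissimilarity matrix (typically `1 - TOM`).
#' @param minSize minimum module size (default 50).
#' @return named character vector gene -> module label (`"M1"`, ... by
#'   decreasing size, or `"grey"`).
#' @export
detectModules <- function(d, minSize = 50L) {
    d <- as.matrix(d)
    genes <- rownames(d)
    if (nrow(d) < minSize) {
        warning("fewer than minSize genes in total; nothing assigned")
        return(setNames(rep("grey", nrow(d)), genes))
    }
    hc <- hclust(as.dist(d), method = "average")
    # tied dissimilarities can leave heights unsorted by ~1e-17, which
    # cutree rejects
    hc$height <- cummax(hc$height)
    maxh <- max(hc$height)
    bigClusters <- function(h) {
        ct <- cutree(hc, h = h)
        sz <- table(ct)
        big <- as.integer(names(sz)[sz >= minSize])
        lapply(big, function(cl) sort(genes[ct == cl]))
    }
    stable <- list()
    h <- 0.99 * maxh
    prev <- bigClusters(h)
    minh <- min(hc$height)
    repeat {
        h <- h * 0.98
        cur <- if (h >= minh) bigClusters(h) else list()
        if (length(cur))
            for (cl in cur)
                if (any(vapply(prev, identical, logical(1), cl)))
                    stable <- c(stable, list(cl))
        prev <- cur
        if (!length(cur)) break
    }
    stable <- unique(stable)
    lab <- setNames(rep("grey", length(genes)), genes)
    if (!length(stable)) return(lab)

    # maximal disjoint stable clusters are the module cores
    ord <- order(-vapply(stable, length, integer(1)),
                 vapply(stable, `[`, character(1), 1))
    cores <- list(); taken <- character(0)
    for (j in ord) {
        cl <- stable[[j]]
        if (!any(cl %in% taken)) {
            cores <- c(cores, list(cl)); taken <- c(taken, cl)
        }
    }

    # dendrogram node membership and parent pointers
    n <- length(genes)
    members <- vector("list", n - 1L)
    parent <- rep(NA_integer_, n - 1L)
    for (i in seq_len(n - 1L)) {
        m <- hc$merge[i, ]
        members[[i]] <- sort(c(
            if (m[1] < 0) genes[-m[1]] else members[[m[1]]],
            if (m[2] < 0) genes[-m[2]] else members[[m[2]]]))
        if (m[1] > 0) parent[m[1]] <- i
        if (m[2] > 0) parent[m[2]] <- i
    }

    # climb each core to the largest branch free of the other cores; a
    # lone core (nothing else to stop it) is additionally capped at the
    # static-cut ceiling so it cannot swallow the whole input
    final <- lapply(seq_along(cores), function(ci) {
        core <- cores[[ci]]
        others <- unlist(cores[-ci])
        node <- which(vapply(members, function(mm)
            length(mm) == length(core) && all(mm == core), logical(1)))[1]
        if (is.na(node)) return(core)
        repeat {
            p <- parent[node]
            if (is.na(p) || any(members[[p]] %in% others) ||
                (length(cores) == 1L && hc$height[p] >= 0.99 * maxh))
                break
            node <- p
        }
        members[[node]]
    })
    rk <- order(-vapply(final, length, integer(1)),
                vapply(final, `[`, character(1), 1))
    for (i in seq_along(rk))
        lab[final[[rk[i]]]] <- paste0("M", i)
    lab
}

# eigengene: first principal component of the per-gene standardised module
# submatrix, sign-aligned with the module mean expression profile
moduleEigengene <- function(expr, genes) {
    x <- expr[genes, , drop = FALSE]
    xs <- t(apply(x, 1, function(r) {
        s <- sd(r); if (isTRUE(s > 0)) (r - mean(r)) / s else r - mean(r)
    }))
    if (length(genes) == 1L) return(as.numeric(xs))
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    mref <- colMeans(xs)
    if (isTRUE(cor(e, mref) < 0)) e <- -e
    as.numeric(e)
}

#' Merge similar modules by eigengene clustering
#'
#' Module eigengenes are clustered with average linkage on
#' `1 - pearson(E_i, E_j)`; modules joined below `cutHeight` are merged
#' and eigengenes recomputed.
#'
#' @param assignment gene -> module labels (from [detectModules()]).
#' @param expr genes x samples matrix covering the assigned genes.
#' @param cutHeight merge height on the eigengene dissimilarity
#'   (default 0.25, i.e. eigengene correlation above 0.75 merges).
#' @param scan optional soft-threshold scan to carry on the result.
#' @param beta the power used (recorded on the result).
#' @return a [ModuleSet-class] with merged labels (`"M1"`, ... by
#'   decreasing size) and the module x sample eigengene matrix.
#' @export
mergeModules <- function(assignment, expr, cutHeight = 0.25,
                         scan = data.frame(), beta = NA_real_) {
    expr <- as.matrix(expr)
    mods <- sort(setdiff(unique(assignment), "grey"))
    if (!length(mods)) {
        return(new("ModuleSet", assignment = assignment,
                   eigengenes = matrix(numeric(0), 0, ncol(expr),
                                       dimnames = list(NULL, colnames(expr))),
                   beta = beta, scan = scan))
    }
    eg <- vapply(mods, function(m)
        moduleEigengene(expr, names(assignment)[assignment == m]),
        numeric(ncol(expr)))
    if (length(mods) > 1L) {
        D <- 1 - cor(eg)
        hc <- hclust(as.dist(D), method = "average")
        grpIdx <- cutree(hc, h = cutHeight)
        merged <- assignment
        for (g in unique(grpIdx)) {
            members <- mods[grpIdx == g]
            merged[assignment %in% members] <- members[1]
        }
        assignment <- merged
        mods <- sort(setdiff(unique(assignment), "grey"))
    }
    sizes <- vapply(mods, function(m) sum(assignment == m), integer(1))
    newLab <- setNames(paste0("M", rank(-sizes, ties.method = "first")), mods)
    out <- assignment
    out[out != "grey"] <- newLab[out[out != "grey"]]
    mods <- sort(unique(newLab))
    eg <- t(vapply(mods, function(m)
        moduleEigengene(expr, names(out)[out == m]), numeric(ncol(expr))))
    colnames(eg) <- colnames(expr)
    new("ModuleSet", assignment = out, eigengenes = eg,
        beta = beta, scan = scan)
}

#' Full coexpression-module construction
#'
#' Soft-threshold scan, adjacency, TOM, adaptive static cut and
#' eigengene merge in one call — the coexpression stage applied to the
#' feature mRNAs and significant DE lncRNAs.
#'
#' @param expr genes x samples matrix.
#' @param minSize minimum module size (default 50).
#' @param mergeHeight eigengene merge height (default 0.25).
#' @param r2Cut scale-free fit threshold (default 0.85).
#' @param betas candidate powers.
#' @return a [ModuleSet-class].
#' @export
coexpressionModules <- function(expr, minSize = 50L, mergeHeight = 0.25,
                                r2Cut = 0.85, betas = 1:20) {
    st <- softThresholdScan(expr, betas = betas, r2Cut = r2Cut)
    expr <- as.matrix(expr)[st$genes, , drop = FALSE]
    a <- adjacencyMatrix(expr, st$beta)
    d <- 1 - tomMatrix(a)
    lab <- detectModules(d, minSize = minSize)
    mergeModules(lab, expr, cutHeight = mergeHeight, scan = st$scan,
                 beta = st$beta)
}
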