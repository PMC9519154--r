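blockExpr <- function(nPer = 60, nBlocks = 2, nS = 40, strength = 2,
                      seed = 1) {
    set.seed(seed)
    lab <- rep(paste0("B", seq_len(nBlocks)), each = nPer)
    x <- matrix(rnorm(nPer * nBlocks * nS, sd = 0.4), nPer * nBlocks, nS)
    for (b in seq_len(nBlocks)) {
        f <- rnorm(nS)
        idx <- which(lab == paste0("B", b))
        x[idx, ] <- x[idx, ] + outer(abs(rnorm(nPer, sd = strength)), f)
    }
    rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
    colnames(x) <- sprintf("s%02d", seq_len(nS))
    list(x = x, truth = setNames(lab, rownames(x)))
}

test_that("soft-threshold scan follows the power and fit rules", {
    be <- blockExpr()
    st <- suppressWarnings(softThresholdScan(be$x))
    sc <- st$scan
    # beta = 1 leaves the correlation matrix untouched
    S <- abs(cor(t(be$x))); diag(S) <- 0
    expect_equal(sc$mean_connectivity[1], mean(rowSums(S)),
                 tolerance = 1e-12)
    # connectivity decreases strictly in beta
    expect_true(all(diff(sc$mean_connectivity) < 0))
    # the chosen power obeys the qualification rule when any qualifies
    elig <- sc$mean_connectivity >= 2 * log(nrow(be$x))
    ok <- elig & sc$signed_r2 > 0.85
    if (any(ok))
        expect_equal(st$beta,
                     sc$beta[ok][which.max(sc$mean_connectivity[ok])])

    # constant genes are excluded with a warning
    xc <- be$x; xc[1, ] <- 1
    expect_warning(st2 <- softThresholdScan(xc), "constant")
    expect_false(rownames(xc)[1] %in% st2$genes)
})

test_that("topological overlap matches hand values and the triple-loop oracle", {
    # 3-node chain: TOM_13 = 0.25 / 1.5 = 1/6
    a <- matrix(0, 3, 3)
    a[1, 2] <- a[2, 1] <- 0.5
    a[2, 3] <- a[3, 2] <- 0.5
    tom <- tomMatrix(a)
    expect_equal(tom[1, 3], 1 / 6)
    expect_equal(diag(tom), rep(1, 3))

    # two identical fully connected nodes overlap maximally
    a2 <- matrix(1, 2, 2); diag(a2) <- 0
    expect_equal(tomMatrix(a2)[1, 2], 1)

    # random instances: symmetry, bounds, exact oracle agreement
    set.seed(5)
    for (rep in 1:3) {
        n <- sample(10:60, 1)
        r <- matrix(runif(n * n), n, n)
        a3 <- (r + t(r)) / 2; diag(a3) <- 0
        tom3 <- tomMatrix(a3)
        expect_true(isSymmetric(tom3))
        expect_true(all(tom3 >= 0 & tom3 <= 1 + 1e-12))
        expect_equal(tom3, tomOracle(a3), tolerance = 1e-12)
    }
})

test_that("module detection recovers planted blocks and respects minSize", {
    # idealized two-block dissimilarity: within 0.1, between 0.9
    lab <- rep(c("A", "B"), each = 60)
    d <- matrix(0.9, 120, 120)
    d[1:60, 1:60] <- 0.1; d[61:120, 61:120] <- 0.1
    diag(d) <- 0
    rownames(d) <- colnames(d) <- sprintf("g%03d", 1:120)
    asg <- detectModules(d, minSize = 50)
    expect_equal(adjustedRand(asg, lab), 1)

    # permuting gene order changes labels only
    perm <- sample(120)
    asg2 <- detectModules(d[perm, perm], minSize = 50)
    expect_equal(adjustedRand(asg2, lab[perm]), 1)

    # impossible minimum size leaves everything unassigned
    expect_warning(asg3 <- detectModules(d[1:30, 1:30], minSize = 50))
    expect_true(all(asg3 == "grey"))
})

test_that("eigengenes summarise modules and drive merging", {
    be <- blockExpr(nPer = 60, nBlocks = 2, seed = 2)
    ms <- suppressWarnings(coexpressionModules(be$x, minSize = 40))
    eg <- moduleEigengenes(ms)
    # eigengene captures more variance of its module than random
    # directions do
    m1 <- names(moduleAssignment(ms))[moduleAssignment(ms) == "M1"]
    xs <- t(scale(t(be$x[m1, ])))
    evar <- function(v) sum((xs %*% v / sqrt(sum(v^2)))^2)
    e1 <- eg[1, ]
    set.seed(9)
    rnd <- replicate(50, evar(rnorm(ncol(xs))))
    expect_gte(evar(e1), max(rnd))

    # correlated eigengenes merge below the cut height, independent ones
    # survive
    set.seed(4)
    nS <- 60
    f1 <- rnorm(nS); f2 <- 0.95 * f1 + sqrt(1 - 0.95^2) * rnorm(nS)
    f3 <- rnorm(nS)
    mk <- function(f, n) t(replicate(n, 2 * f + rnorm(nS, sd = 0.4)))
    x <- rbind(mk(f1, 60), mk(f2, 60), mk(f3, 60))
    rownames(x) <- sprintf("g%03d", 1:180); colnames(x) <- paste0("s", 1:nS)
    lab <- setNames(rep(c("M1", "M2", "M3"), each = 60), rownames(x))
    merged <- mergeModules(lab, x, cutHeight = 0.25)
    asg <- moduleAssignment(merged)
    # the two factor-correlated modules collapse; the third stays apart
    expect_equal(length(unique(asg[1:120])), 1L)
    expect_equal(length(unique(asg)), 2L)
})

test_that("no modules are reported on unstructured data", {
    ok <- vapply(1:5, function(s) {
        set.seed(400 + s)
        x <- matrix(rnorm(200 * 60), 200, 60,
                    dimnames = list(sprintf("g%03d", 1:200),
                                    paste0("s", 1:60)))
        asg <- suppressWarnings(
            moduleAssignment(coexpressionModules(x, minSize = 50)))
        all(asg == "grey")
    }, logical(1))
    expect_gte(mean(ok), 0.8)
})
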