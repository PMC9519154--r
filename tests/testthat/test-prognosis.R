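handSurv <- function() {
    # 14 samples, distinct times, 11 events
    data.frame(sample = paste0("s", 1:14),
               time_years = c(1.2, 2.5, 0.8, 3.1, 4.4, 2.0, 5.2, 3.8,
                              1.6, 4.9, 0.5, 2.9, 3.4, 6.1),
               event = c(1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 1, 1, 0, 1),
               stringsAsFactors = FALSE)
}

simSurvData <- function(seed, nCase = 150, coefs = c(-1.13, -1.41),
                        nNoise = 0) {
    sim <- simulateCrosstalkStudy(simConfig(nCase = nCase,
                                            prognosticCoefs = coefs,
                                            seed = seed))
    sv <- sim$survival
    prog <- sim$truth$prognostic_genes
    cm <- assayOf(sim$mrna)
    genes <- prog
    if (nNoise > 0) {
        pool <- setdiff(rownames(cm),
                        c(prog, names(unlist(sim$truth$module_assignments))))
        set.seed(seed)
        genes <- c(prog, sample(pool, nNoise))
    }
    x <- log2(cm[genes, sv$sample, drop = FALSE] + 1)
    z <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
    list(z = z, surv = sv, prog = prog, coefs = coefs)
}

test_that("single-covariate Cox fit matches a Newton oracle", {
    sv <- handSurv()
    set.seed(2)
    x <- c(0.3, -1.2, 0.8, 0.1, -0.5, 1.7, -0.9, 0.4, -0.2, 1.1,
           0.6, -1.4, 0.9, -0.3)
    expr <- matrix(x, 1, 14, dimnames = list("g1", sv$sample))
    uni <- suppressWarnings(univariateCox(expr, sv, pCut = 1))
    expect_equal(uni$coef, coxNewtonOracle(sv$time_years, sv$event, x),
                 tolerance = 1e-6)
    expect_equal(uni$hr, exp(uni$coef))

    # constant gene is dropped with a warning
    expr2 <- rbind(expr, g2 = rep(1, 14))
    expect_warning(uni2 <- univariateCox(expr2, sv, pCut = 1), "constant")
    expect_equal(uni2$gene, "g1")
})

test_that("univariate screen holds its nominal false-positive rate", {
    rates <- vapply(1:5, function(s) {
        d <- simSurvData(700 + s, nCase = 120, coefs = c(0, 0), nNoise = 38)
        uni <- suppressWarnings(univariateCox(d$z, d$surv, pCut = 0.01))
        mean(uni$p < 0.01)
    }, numeric(1))
    expect_lt(mean(rates), 0.05)

    # and catches a planted prognostic gene at moderate n
    hits <- vapply(1:5, function(s) {
        d <- simSurvData(800 + s, nCase = 150)
        uni <- suppressWarnings(univariateCox(d$z, d$surv, pCut = 0.01))
        all(uni$keep[match(d$prog, uni$gene)])
    }, logical(1))
    expect_gte(mean(hits), 0.8)
})

test_that("backward stepwise keeps informative genes and lowers AIC", {
    d <- simSurvData(42, nCase = 300, nNoise = 8)
    model <- stepwiseCox(d$z, d$surv)
    expect_true(all(d$prog %in% modelGenes(model)))
    # final AIC no worse than the full starting model
    y <- survival::Surv(d$surv$time_years, d$surv$event)
    full <- survival::coxph(y ~ t(d$z), ties = "breslow")
    aicFull <- -2 * full$loglik[2] + 2 * length(coef(full))
    expect_lte(model@aic, aicFull)

    # single-gene input: no-op iff dropping it raises AIC
    d1 <- d$z[d$prog[1], , drop = FALSE]
    m1 <- stepwiseCox(d1, d$surv)
    expect_equal(modelGenes(m1), d$prog[1])
})

test_that("risk scores split at the training median with exact halves", {
    # 82 distinct scores: 41 high, 41 low
    set.seed(77)
    x <- matrix(sample(seq(-3, 3, length.out = 82)), 1, 82,
                dimnames = list("g1", paste0("s", 1:82)))
    model <- new("RiskModel", genes = "g1", coefficients = 1,
                 aic = 0, cutoff = median(x), center = c(g1 = 0),
                 scale = c(g1 = 1))
    split <- riskSplit(model, x)
    expect_equal(as.integer(table(split$risk)), c(41L, 41L))

    # the published two-gene arithmetic: x = (1,1) scores -2.54
    m2 <- new("RiskModel", genes = c("a", "b"),
              coefficients = c(-1.13, -1.41), aic = 0, cutoff = 0,
              center = c(a = 0, b = 0), scale = c(a = 1, b = 1))
    xx <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "s1"))
    expect_equal(unname(riskScores(m2, xx)), -2.54)

    # all-tied scores fall to low risk with a warning
    xt <- matrix(1, 1, 5, dimnames = list("g1", paste0("s", 1:5)))
    mt <- new("RiskModel", genes = "g1", coefficients = 1, aic = 0,
              cutoff = 1, center = c(g1 = 0), scale = c(g1 = 1))
    expect_warning(st <- riskSplit(mt, xt))
    expect_true(all(st$risk == "low"))

    expect_error(riskScores(m2, xt), "missing")
})

test_that("model building uses training rows only", {
    d <- simSurvData(55, nCase = 200, nNoise = 5)
    rm1 <- buildRiskModel(d$z, d$surv)
    # perturbing the test-set expression leaves the fitted model untouched
    z2 <- d$z
    testCols <- d$surv$sample[d$surv$dataset != "train"]
    z2[, testCols] <- z2[, testCols] + 5
    rm2 <- buildRiskModel(z2, d$surv)
    expect_identical(modelGenes(rm1$model), modelGenes(rm2$model))
    expect_equal(modelCoefficients(rm1$model),
                 modelCoefficients(rm2$model))
    expect_equal(modelCutoff(rm1$model), modelCutoff(rm2$model))
})

test_that("KM and log-rank handle the standard and degenerate cases", {
    sv <- handSurv()
    # closed form: survival after the first death among n at risk
    fit <- survival::survfit(survival::Surv(time_years, event) ~ 1,
                             data = sv)
    firstEvent <- min(sv$time_years[sv$event == 1])
    atRisk <- sum(sv$time_years >= firstEvent)
    expect_equal(summary(fit, times = firstEvent)$surv, 1 - 1 / atRisk)

    # identical event patterns in both groups: statistic 0, p = 1
    sv2 <- rbind(sv, sv)
    sv2$sample <- paste0("s", seq_len(nrow(sv2)))
    kl <- kmLogrank(sv2, rep(c("high", "low"), each = nrow(sv)))
    expect_equal(kl$chisq, 0, tolerance = 1e-12)
    expect_equal(kl$p, 1, tolerance = 1e-12)

    # no events at all: curves flat, statistic undefined
    sv0 <- sv; sv0$event <- 0
    kl0 <- kmLogrank(sv0, rep(c("high", "low"), each = nrow(sv) / 2))
    expect_true(is.na(kl0$chisq))
    expect_error(kmLogrank(sv, rep("high", nrow(sv))), "two non-empty")
})

test_that("the risk score acts as an independent prognostic factor", {
    d <- simSurvData(91, nCase = 200)
    score <- as.numeric(crossprod(d$z[d$prog, ], d$coefs))
    fr <- independentPrognostic(d$surv, score)
    expect_equal(fr$hr, exp(fr$coef), tolerance = 1e-12)
    row <- fr[fr$covariate == "riskScore", ]
    expect_gt(row$hr, 1)   # higher score = higher hazard by construction
    expect_lt(row$p, 0.05)
})

test_that("time-dependent AUC is calibrated at its extremes", {
    # perfectly separating marker without censoring
    sv <- data.frame(sample = paste0("s", 1:40),
                     time_years = c(seq(0.5, 2, length.out = 20),
                                    seq(6, 9, length.out = 20)),
                     event = 1)
    marker <- c(rep(2, 20), rep(-2, 20))
    td <- timeDependentAUC(sv, marker, times = 4)
    expect_equal(td$auc, 1)

    # evaluation time past follow-up leaves no controls
    td2 <- timeDependentAUC(sv, marker, times = 20)
    expect_true(is.na(td2$auc))

    # multi-index table returns one AUC per prognostic index
    d <- simSurvData(17, nCase = 120)
    score <- as.numeric(crossprod(d$z[d$prog, ], d$coefs))
    mi <- multiIndexAUC(d$surv, score, refTime = 5)
    expect_equal(mi$index, c("riskScore", "braaksc", "ceradsc",
                             "dcfdx_lv"))
    expect_true(all(mi$auc > 0 & mi$auc < 1, na.rm = TRUE))
})
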