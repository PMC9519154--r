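#' Univariate Cox screen over candidate genes
#'
#' One single-covariate proportional-hazards fit per gene (Breslow tie
#' handling, partial-likelihood maximisation via [survival::coxph()]);
#' genes with Wald `p < pCut` form the keep set. Constant and
#' non-converging genes are dropped with a warning.
#'
#' @param expr genes x samples matrix of (standardised) expression,
#'   columns matching `surv$sample`.
#' @param surv data.frame with `sample`, `time_years`, `event`.
#' @param pCut screen threshold (default 0.01).
#' @return data.frame `gene`, `coef`, `hr`, `p`, `keep`.
#' @export
univariateCox <- function(expr, surv, pCut = 0.01) {
    expr <- as.matrix(expr)[, surv$sample, drop = FALSE]
    if (sum(surv$event) < 10L)
        stop("need at least 10 events for the univariate screen")
    y <- survival::Surv(surv$time_years, surv$event)
    rows <- lapply(rownames(expr), function(g) {
        x <- expr[g, ]
        if (isTRUE(sd(x) == 0) || !isTRUE(sd(x) > 0)) {
            warning("constant gene dropped: ", g)
            return(NULL)
        }
        fit <- tryCatch(survival::coxph(y ~ x, ties = "breslow"),
                        warning = function(w) NULL, error = function(e) NULL)
        if (is.null(fit) || !is.finite(coef(fit))) {
            warning("Cox fit did not converge; gene dropped: ", g)
            return(NULL)
        }
        s <- summary(fit)
        data.frame(gene = g, coef = unname(coef(fit)),
                   hr = unname(exp(coef(fit))),
                   p = s$coefficients[1, "Pr(>|z|)"],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no gene could be fitted")
    out$keep <- out$p < pCut
    out
}

#' Backward stepwise multivariate Cox by lowest AIC
#'
#' Starts from the full multivariate model over the kept genes and
#' repeatedly applies the single-covariate drop that lowers the
#' partial-likelihood AIC (`-2 logPL + 2 * #covariates`) the most,
#' stopping when no drop lowers it. The accepted AIC sequence is
#' strictly decreasing by construction.
#'
#' @param expr genes x samples matrix (training samples).
#' @param surv training survival table (`sample`, `time_years`, `event`).
#' @param genes genes to start from (default: all rows of `expr`).
#' @return a [RiskModel-class] whose cutoff is the median training risk
#'   score; `center`/`scale` are zero/one (standardise upstream, e.g.
#'   via [buildRiskModel()]).
#' @export
stepwiseCox <- function(expr, surv, genes = rownames(expr)) {
    expr <- as.matrix(expr)[, surv$sample, drop = FALSE]
    if (!length(genes)) stop("empty starting gene set")
    y <- survival::Surv(surv$time_years, surv$event)
    fitFor <- function(gs) {
        if (!length(gs)) return(NULL)
        X <- t(expr[gs, , drop = FALSE])
        tryCatch(survival::coxph(y ~ X, ties = "breslow"),
                 error = function(e) NULL,
                 warning = function(w) NULL)
    }
    aicOf <- function(fit) if (is.null(fit) || any(!is.finite(coef(fit))))
        Inf else as.numeric(-2 * fit$loglik[2] + 2 * length(coef(fit)))
    current <- genes
    fit <- fitFor(current)
    # a collinear or over-parameterised start: peel genes off the end
    # (callers pass them ranked, strongest first) until the fit is sound
    while ((is.null(fit) || !is.finite(aicOf(fit))) && length(current) > 1L) {
        current <- current[-length(current)]
        fit <- fitFor(current)
    }
    if (is.null(fit)) stop("no multivariate Cox model could be fitted")
    aic <- aicOf(fit)
    repeat {
        if (length(current) == 1L) {
            # dropping the last covariate means the null model
            null2 <- -2 * fit$loglik[1]
            if (null2 < aic)
                stop("stepwise selection eliminated every gene; ",
                     "relax the univariate threshold")
            break
        }
        cand <- lapply(seq_along(current), function(i) {
            f <- fitFor(current[-i])
            list(drop = current[i], fit = f, aic = aicOf(f))
        })
        aics <- vapply(cand, `[[`, numeric(1), "aic")
        best <- which.min(aics)
        if (aics[best] >= aic) break
        stopifnot(aics[best] < aic)  # accepted steps strictly decrease AIC
        current <- setdiff(current, cand[[best]]$drop)
        fit <- cand[[best]]$fit
        aic <- aics[best]
    }
    cf <- as.numeric(coef(fit))
    score <- as.numeric(crossprod(expr[current, , drop = FALSE], cf))
    new("RiskModel", genes = current, coefficients = cf, aic = aic,
        cutoff = median(score),
        center = setNames(rep(0, length(current)), current),
        scale = setNames(rep(1, length(current)), current))
}

#' Build a risk model from a survival table with a train/test split
#'
#' Standardises each candidate gene on the training samples, runs the
#' univariate screen there, then the backward stepwise multivariate fit.
#' The model (genes, coefficients, standardisation, median cutoff) is
#' determined by the training rows only.
#'
#' @param expr genes x samples expression matrix (e.g. `log2(TPM + 1)`
#'   of the chosen module's genes).
#' @param surv survival table with a `dataset` column (`train`/`test`).
#' @param uniP univariate screen threshold (default 0.01).
#' @param maxGenes cap on the stepwise starting set (smallest univariate
#'   p first); keeps the events-per-variable ratio of the multivariate
#'   fit workable when many correlated genes pass the screen.
#' @param relaxIfEmpty when no gene passes the screen, fall back to the
#'   `maxGenes` smallest-p genes with a warning instead of stopping
#'   (used by the pipeline so a run always yields a model).
#' @return list: `model` ([RiskModel-class]), `univariate` (screen
#'   table), `train`, `test` (the split survival tables).
#' @export
buildRiskModel <- function(expr, surv, uniP = 0.01, maxGenes = 15L,
                           relaxIfEmpty = FALSE) {
    expr <- as.matrix(expr)
    train <- surv[surv$dataset == "train", , drop = FALSE]
    test <- surv[surv$dataset != "train", , drop = FALSE]
    xt <- expr[, train$sample, drop = FALSE]
    ctr <- rowMeans(xt)
    scl <- apply(xt, 1, sd)
    use <- scl > 0
    if (!all(use)) warning(sum(!use), " constant gene(s) dropped")
    ctr <- ctr[use]; scl <- scl[use]
    zTrain <- (xt[use, , drop = FALSE] - ctr) / scl
    uni <- univariateCox(zTrain, train, pCut = uniP)
    kept <- uni$gene[uni$keep][order(uni$p[uni$keep])]
    if (!length(kept)) {
        if (!relaxIfEmpty)
            stop("no gene passed the univariate screen at p < ", uniP)
        warning("no gene passed the univariate screen at p < ", uniP,
                "; falling back to the ", maxGenes, " smallest-p genes")
        kept <- uni$gene[order(uni$p)]
    }
    kept <- head(kept, maxGenes)
    model <- stepwiseCox(zTrain[kept, , drop = FALSE], train, kept)
    model@center <- ctr[model@genes]
    model@scale <- scl[model@genes]
    list(model = model, univariate = uni, train = train, test = test)
}

#' Risk scores under a fitted model
#'
#' `riskScore(x) = sum_k coef(k) * x(k)` after applying the model's
#' training standardisation.
#'
#' @param model a [RiskModel-class].
#' @param expr genes x samples matrix containing the model genes.
#' @return named numeric vector of scores.
#' @export
riskScores <- function(model, expr) {
    expr <- as.matrix(expr)
    miss <- setdiff(model@genes, rownames(expr))
    if (length(miss))
        stop("model genes missing from expression: ",
             paste(miss, collapse = ", "))
    z <- (expr[model@genes, , drop = FALSE] - model@center) / model@scale
    setNames(as.numeric(crossprod(z, model@coefficients)), colnames(expr))
}

#' Median split into high- and low-risk groups
#'
#' Samples with score strictly above the training-median cutoff are
#' high-risk; at the cutoff (including an all-tied degenerate score
#' vector) samples fall to low-risk, with a warning when everything
#' ties. With an even number of distinct training scores the training
#' set splits into exact halves.
#'
#' @param model a [RiskModel-class].
#' @param expr genes x samples matrix.
#' @param samples optional subset of samples to classify.
#' @return data.frame `sample`, `score`, `risk` (`high`/`low`).
#' @export
riskSplit <- function(model, expr, samples = colnames(expr)) {
    sc <- riskScores(model, as.matrix(expr)[, samples, drop = FALSE])
    if (length(unique(sc)) == 1L)
        warning("all risk scores are equal; every sample is low-risk")
    data.frame(sample = samples, score = sc,
               risk = ifelse(sc > model@cutoff, "high", "low"),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' @param surv survival table (`time_years`, `event`).
#' @param class per-sample group labels (two levels expected).
#' @return list: `fit` (a [survival::survfit()] object), `chisq`, `p`
#'   (both `NA` when no events occurred).
#' @export
kmLogrank <- function(surv, class) {
    cls <- as.factor(class)
    if (any(table(cls) == 0L) || nlevels(cls) < 2L)
        stop("need two non-empty classes")
    fit <- survival::survfit(survival::Surv(time_years, event) ~ cls,
                             data = cbind(surv, cls = cls))
    if (sum(surv$event) == 0L)
        return(list(fit = fit, chisq = NA_real_, p = NA_real_))
    sd <- survival::survdiff(survival::Surv(time_years, event) ~ cls,
                             data = cbind(surv, cls = cls))
    list(fit = fit, chisq = sd$chisq,
         p = pchisq(sd$chisq, df = nlevels(cls) - 1L, lower.tail = FALSE))
}

#' Multivariate independent-prognostic (forest plot) quantities
#'
#' One multivariate Cox fit of the risk score together with the clinical
#' severity covariates; per covariate the hazard ratio `exp(coef)`, its
#' Wald 95% confidence interval and p-value.
#'
#' @param surv survival table with `braaksc`, `ceradsc`, `dcfdx_lv`.
#' @param score per-sample risk score aligned with `surv` rows.
#' @return data.frame `covariate`, `coef`, `hr`, `lower95`, `upper95`,
#'   `p`.
#' @export
independentPrognostic <- function(surv, score) {
    if (sum(surv$event) < 10L) stop("need at least 10 events")
    df <- data.frame(time = surv$time_years, event = surv$event,
                     riskScore = score, braaksc = surv$braaksc,
                     ceradsc = surv$ceradsc, dcfdx_lv = surv$dcfdx_lv)
    fit <- survival::coxph(survival::Surv(time, event) ~ riskScore +
                               braaksc + ceradsc + dcfdx_lv,
                           data = df, ties = "breslow")
    s <- summary(fit)$coefficients
    data.frame(covariate = rownames(s), coef = s[, "coef"],
               hr = exp(s[, "coef"]),
               lower95 = exp(s[, "coef"] - qnorm(0.975) * s[, "se(coef)"]),
               upper95 = exp(s[, "coef"] + qnorm(0.975) * s[, "se(coef)"]),
               p = s[, "Pr(>|z|)"], row.names = NULL,
               stringsAsFactors = FALSE)
}

# KM estimator of the censoring survival G(t); returns an evaluator with
# optional left limits
censoringSurvival <- function(time, event) {
    fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
    function(t, left = FALSE) {
        tt <- if (left) t - 1e-9 * max(1, abs(t)) else t
        vapply(tt, function(u) {
            if (u < min(fit$time)) return(1)
            idx <- findInterval(u, fit$time)
            if (idx == 0L) 1 else fit$surv[idx]
        }, numeric(1))
    }
}

#' Time-dependent AUC with inverse-probability-of-censoring weights
#'
#' Cumulative-case / dynamic-control AUC at each requested time:
#' cases are samples with an observed event by `t` (weighted by
#' `1 / G(T_i-)`), controls those still at risk after `t` (weighted by
#' `1 / G(t)`), with `G` the Kaplan-Meier estimator of the censoring
#' distribution. Ties in the marker count one half.
#'
#' @param surv survival table (`time_years`, `event`).
#' @param score per-sample marker aligned with `surv` rows.
#' @param times evaluation times (years).
#' @return data.frame `time`, `auc`, `n_case`, `n_control`; `auc` is
#'   `NA` when either risk set is empty.
#' @export
timeDependentAUC <- function(surv, score, times) {
    time <- surv$time_years; event <- surv$event
    G <- censoringSurvival(time, event)
    do.call(rbind, lapply(times, function(t0) {
        case <- time <= t0 & event == 1
        ctrl <- time > t0
        if (!any(case) || !any(ctrl))
            return(data.frame(time = t0, auc = NA_real_,
                              n_case = sum(case), n_control = sum(ctrl)))
        wc <- 1 / G(time[case], left = TRUE)
        wk <- rep(1 / G(t0), sum(ctrl))
        mi <- score[case]; mj <- score[ctrl]
        cmp <- outer(mi, mj, ">") + 0.5 * outer(mi, mj, "==")
        auc <- sum(outer(wc, wk) * cmp) / (sum(wc) * sum(wk))
        data.frame(time = t0, auc = auc, n_case = sum(case),
                   n_control = sum(ctrl))
    }))
}

#' Multi-index AUC table at a reference time
#'
#' The time-dependent AUC of the risk score and of each clinical
#' severity covariate at a single reference time, for side-by-side
#' comparison of prognostic indices.
#'
#' @param surv survival table with the clinical covariates.
#' @param score per-sample risk score.
#' @param refTime reference time in years (default 5).
#' @return data.frame `index`, `auc`.
#' @export
multiIndexAUC <- function(surv, score, refTime = 5) {
    idx <- list(riskScore = score, braaksc = surv$braaksc,
                ceradsc = surv$ceradsc, dcfdx_lv = surv$dcfdx_lv)
    data.frame(index = names(idx),
               auc = vapply(idx, function(m)
                   timeDependentAUC(surv, m, refTime)$auc, numeric(1)),
               row.names = NULL, stringsAsFactors = FALSE)
}
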