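#' Simulate a pathway collection with crosstalk
#'
#' Draws `nPathways` gene sets from the mRNA universe. Neighbouring
#' pathways (i, i+1 mod n) share `round(crosstalkOverlap * size)` genes, so
#' crosstalk is realised as shared membership — exactly how the merged
#' global network later connects pathway subgraphs. Within each pathway an
#' interaction graph is drawn as a random spanning path (guaranteeing
#' connectivity) plus Erdős–Rényi extra edges with probability `1/(m-1)`,
#' giving expected degree close to 3.
#'
#' @param cfg a [SimConfig-class].
#' @return a [PathwayCollection-class]. Deterministic given `cfg@seed`.
#' @export
simulatePathways <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    withSeed(cfg@seed + 101L, {
        n <- cfg@nPathways
        rng <- cfg@pathwaySizeRange
        sizes <- if (rng[1] == rng[2]) rep(rng[1], n)
                 else sample(seq(rng[1], rng[2]), n, replace = TRUE)
        universe <- sprintf("G%04d", seq_len(cfg@nGenes))

        # shared blocks between unordered neighbour pairs; a 2-cycle is a
        # single pair, so it gets a single shared block
        nPairs <- if (n >= 3L) n else if (n == 2L) 1L else 0L
        s <- if (nPairs) vapply(seq_len(nPairs), function(i)
            as.integer(round(cfg@crosstalkOverlap * sizes[i])), integer(1))
        else integer(0)
        prevBlock <- function(i) if (n >= 3L) ((i - 2L) %% n) + 1L
                                 else if (n == 2L && i == 2L) 1L else 0L
        nextBlock <- function(i) if (n >= 3L) i
                                 else if (n == 2L && i == 1L) 1L else 0L
        fresh <- vapply(seq_len(n), function(i) {
            sz <- sizes[i]
            pb <- prevBlock(i); nb <- nextBlock(i)
            sz - (if (pb) s[pb] else 0L) - (if (nb) s[nb] else 0L)
        }, numeric(1))
        if (any(fresh < 0))
            stop("crosstalkOverlap too large for pathwaySizeRange")
        need <- sum(s) + sum(fresh)
        if (need > cfg@nGenes)
            stop("gene universe too small: ", need, " distinct members needed, ",
                 cfg@nGenes, " genes available")

        pool <- sample(universe)
        take <- local({ pos <- 0L; function(k) {
            out <- pool[pos + seq_len(k)]; pos <<- pos + k; out } })
        blocks <- lapply(s, take)
        members <- lapply(seq_len(n), function(i) {
            pb <- prevBlock(i); nb <- nextBlock(i)
            sort(c(if (pb) blocks[[pb]], if (nb && nb != pb) blocks[[nb]],
                   take(fresh[i])))
        })

        ids <- sprintf("P%02d", seq_len(n))
        edges <- do.call(rbind, lapply(seq_len(n), function(i) {
            g <- members[[i]]; m <- length(g)
            if (m < 2L) return(NULL)
            perm <- sample(g)
            e <- cbind(perm[-m], perm[-1])
            if (m > 2L) {
                pairs <- t(combn(g, 2L))
                keep <- runif(nrow(pairs)) < 1 / (m - 1)
                e <- rbind(e, pairs[keep, , drop = FALSE])
            }
            a <- pmin(e[, 1], e[, 2]); b <- pmax(e[, 1], e[, 2])
            dup <- duplicated(paste(a, b))
            data.frame(pathway = ids[i], from = a[!dup], to = b[!dup],
                       stringsAsFactors = FALSE)
        }))
        ord <- order(edges$pathway, edges$from, edges$to)
        PathwayCollection(ids, members, sprintf("Pathway %02d", seq_len(n)),
                          edges[ord, , drop = FALSE])
    })
}

#' Simulate count matrices with planted structure
#'
#' Generates mRNA and lncRNA count matrices on the log2 scale — baseline
#' `mu_g ~ U(3,8)` for mRNAs (`U(2,6)` for lncRNAs) plus planted effects
#' plus gene-level noise whose variance matches a negative-binomial
#' dispersion of `nbDispersion` — then exponentiates and Poisson-rounds,
#' yielding overdispersed integer counts.
#'
#' Planted structure, recorded in the returned truth list:
#' * `nDysregulated` pathways whose members are shifted by `effectDelta`
#'   log2 units in the case group on `affectedFraction` of their genes;
#' * `nModules` coexpression modules (pathway mRNAs + planted DE lncRNAs)
#'   driven by per-module latent factors with half-normal loadings;
#' * up/down DE lncRNAs at `+/- lncDeLfc`;
#' * two prognostic genes, members of dysregulated pathways and of the
#'   first planted module;
#' * an autophagy annotation list concentrated on dysregulated pathways
#'   and the first module, with a small background rate elsewhere.
#'
#' Batch labels are assigned round-robin and, unless `batchEffectSd > 0`,
#' carry no effect.
#'
#' @param cfg a [SimConfig-class].
#' @param pathways result of [simulatePathways()].
#' @return list with `mrna` and `lnc`
#'   ([SummarizedExperiment::SummarizedExperiment]s carrying `group` and
#'   `batch` in `colData` and `length`/`type` in `rowData`) and `truth`.
#' @export
simulateCounts <- function(cfg, pathways) {
    stopifnot(is(cfg, "SimConfig"), is(pathways, "PathwayCollection"))
    withSeed(cfg@seed + 202L, {
        nS <- cfg@nCase + cfg@nControl
        samples <- sprintf("S%03d", seq_len(nS))
        group <- c(rep("AD", cfg@nCase), rep("control", cfg@nControl))
        batch <- paste0("b", (seq_len(nS) - 1L) %% cfg@nBatches)
        mrnas <- sprintf("G%04d", seq_len(cfg@nGenes))
        lncs <- sprintf("LNC%04d", seq_len(cfg@nLnc))
        pathUnion <- sort(unique(unlist(pathways@genes)))

        dys <- if (cfg@nDysregulated > 0L)
            sort(sample(pathways@ids, cfg@nDysregulated)) else character(0)
        affected <- if (cfg@effectDelta != 0)
            sort(unique(unlist(lapply(dys, function(p) {
                g <- pathwayGenes(pathways, p)
                sample(g, round(cfg@affectedFraction * length(g)))
            })))) else character(0)

        nDe <- round(cfg@lncDeFraction * cfg@nLnc)
        deIds <- if (nDe > 0) sort(sample(lncs, nDe)) else character(0)
        deSign <- setNames(rep(c(1, -1), length.out = length(deIds)), deIds)

        # prognostic genes sit in dysregulated pathways (hence among the
        # crosstalk genes) and in the first planted module
        progPool <- if (length(dys))
            unique(unlist(pathways@genes[match(dys, pathways@ids)]))
        else pathUnion
        prog <- sort(sample(progPool, 2L))

        assignment <- character(0)
        moduleGenes <- list()
        if (cfg@nModules > 0L) {
            lncPer <- min(floor(cfg@moduleSize / 6),
                          if (length(deIds)) floor(length(deIds) / cfg@nModules)
                          else 0L)
            mPer <- cfg@moduleSize - lncPer
            # module 1 (the autophagy/prognosis module) is seeded with the
            # UNAFFECTED members of the dysregulated pathways, so it both
            # survives the feature-mRNA restriction applied before
            # coexpression analysis and leaves the planted mean-shift
            # genes free of the module factor's variance; the remainder
            # comes from mRNAs outside the pathway universe
            dysMembers <- setdiff(unique(unlist(
                pathways@genes[match(dys, pathways@ids)])),
                c(prog, affected))
            mPool <- setdiff(pathUnion, c(prog, dysMembers, affected))
            spare <- setdiff(mrnas, pathUnion)
            lncPool <- deIds
            lncSpare <- setdiff(lncs, deIds)
            for (k in seq_len(cfg@nModules)) {
                wantM <- if (k == 1L) mPer - 2L else mPer
                gM <- if (k == 1L && length(dysMembers)) {
                    first <- sample(dysMembers, min(wantM, length(dysMembers)))
                    rest <- wantM - length(first)
                    c(first, if (rest > 0) sample(spare, min(rest,
                                                             length(spare))))
                } else if (wantM <= length(mPool)) sample(mPool, wantM)
                      else c(mPool, sample(spare, wantM - length(mPool)))
                if (length(gM) < wantM)
                    gM <- c(gM, sample(setdiff(spare, gM),
                                       wantM - length(gM)))
                mPool <- setdiff(mPool, gM); spare <- setdiff(spare, gM)
                gL <- if (lncPer <= length(lncPool)) sample(lncPool, lncPer)
                      else c(lncPool, sample(lncSpare, lncPer - length(lncPool)))
                lncPool <- setdiff(lncPool, gL); lncSpare <- setdiff(lncSpare, gL)
                g <- c(if (k == 1L) prog, gM, gL)
                moduleGenes[[k]] <- g
                assignment[g] <- paste0("M", k)
            }
        }

        sdLog2 <- sqrt(log1p(cfg@nbDispersion)) / log(2)
        simBlock <- function(ids, muLo, muHi) {
            mu <- runif(length(ids), muLo, muHi)
            matrix(mu, length(ids), nS) +
                matrix(rnorm(length(ids) * nS, sd = sdLog2), length(ids), nS)
        }
        logM <- simBlock(mrnas, 3, 8); rownames(logM) <- mrnas
        logL <- simBlock(lncs, 2, 6); rownames(logL) <- lncs
        # module members sit in the low-to-mid expression stratum so that
        # the latent-factor swings do not dominate per-sample library
        # totals (which would leak compositional noise into every TPM
        # value)
        modM <- intersect(names(assignment), mrnas)
        if (length(modM))
            logM[modM, ] <- matrix(runif(length(modM), 4.5, 6.5),
                                   length(modM), nS) +
                matrix(rnorm(length(modM) * nS, sd = sdLog2),
                       length(modM), nS)

        isCase <- group == "AD"
        if (length(affected))
            logM[affected, isCase] <- logM[affected, isCase] + cfg@effectDelta
        if (length(deIds))
            logL[deIds, isCase] <- logL[deIds, isCase] +
                deSign[deIds] * cfg@lncDeLfc

        for (k in seq_along(moduleGenes)) {
            g <- moduleGenes[[k]]
            fac <- rnorm(nS)
            load <- abs(rnorm(length(g), sd = cfg@moduleFactorSd))
            # prognostic genes are module members with moderate loadings:
            # a two-gene signature is only meaningful if the genes carry
            # partially independent information, not as near-duplicates
            # of the module factor
            inProg <- match(intersect(prog, g), g)
            if (length(inProg))
                load[inProg] <- abs(rnorm(length(inProg), sd = 1.5))
            # half mean-compensation on the count scale keeps the
            # factor's average library inflation bounded without pushing
            # strongly loaded genes onto the Poisson floor
            add <- outer(load, fac) - load^2 * log(2) / 4
            gm <- intersect(g, mrnas); gl <- intersect(g, lncs)
            logM[gm, ] <- logM[gm, ] + add[match(gm, g), ]
            logL[gl, ] <- logL[gl, ] + add[match(gl, g), ]
        }

        if (cfg@batchEffectSd > 0) {
            off <- rnorm(cfg@nBatches, sd = cfg@batchEffectSd)
            bIdx <- as.integer(factor(batch, levels = paste0("b",
                seq_len(cfg@nBatches) - 1L)))
            logM <- logM + matrix(off[bIdx], nrow(logM), nS, byrow = TRUE)
            logL <- logL + matrix(off[bIdx], nrow(logL), nS, byrow = TRUE)
        }

        toCounts <- function(lx) {
            # cap at 2^20 counts: keeps extreme latent-factor draws within
            # integer range without touching realistic expression levels
            m <- matrix(rpois(length(lx), lambda = 2^pmin(lx, 20)),
                        nrow(lx), ncol(lx))
            dimnames(m) <- dimnames(lx); storage.mode(m) <- "integer"; m
        }
        cm <- toCounts(logM); cl <- toCounts(logL)

        lenM <- as.integer(round(runif(length(mrnas), 500, 8000)))
        lenL <- as.integer(round(runif(length(lncs), 300, 4000)))

        aut <- unique(c(
            unlist(lapply(dys, function(p) {
                g <- pathwayGenes(pathways, p)
                sample(g, round(0.4 * length(g)))
            })),
            if (length(moduleGenes)) {
                g1 <- intersect(moduleGenes[[1]], pathUnion)
                sample(g1, round(0.5 * length(g1)))
            },
            {
                rest <- setdiff(pathUnion, unlist(pathways@genes[
                    match(dys, pathways@ids)]))
                if (length(rest)) sample(rest, round(0.03 * length(rest)))
            }))
        aut <- sort(aut)

        cd <- S4Vectors::DataFrame(group = group, batch = batch,
                                   row.names = samples)
        mk <- function(m, len, type) SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = m), colData = cd,
            rowData = S4Vectors::DataFrame(length = len, type = type,
                                           row.names = rownames(m)))
        truth <- list(
            dysregulated_pathway_ids = dys,
            affected_genes = affected,
            module_assignments = as.list(assignment),
            de_lnc = as.list(deSign),
            prognostic_genes = prog,
            prognostic_coefs = cfg@prognosticCoefs,
            autophagy_genes = aut)
        list(mrna = mk(cm, lenM, "mRNA"), lnc = mk(cl, lenL, "lncRNA"),
             truth = truth)
    })
}

#' Simulate survival outcomes for the case samples
#'
#' Event times for each case sample are exponential with rate
#' `baselineHazard * exp(sum_k coef_k * z_k)`, where `z_k` is the
#' per-gene standardised log2 expression of planted prognostic gene `k`.
#' Censoring is uniform on `(0, censorHorizon)`. Neuropathological and
#' clinical severity covariates (`braaksc` 0-6, `ceradsc` 1-4, `dcfdx_lv`
#' 1-6) are drawn around means that increase weakly with the standardised
#' log-hazard, and a `dataset` column splits cases 40%/60% into
#' train/test.
#'
#' @param cfg a [SimConfig-class].
#' @param mrna the mRNA `SummarizedExperiment` from [simulateCounts()].
#' @param truth the truth list from [simulateCounts()].
#' @return data.frame: `sample`, `time_years`, `event`, `braaksc`,
#'   `ceradsc`, `dcfdx_lv`, `dataset`.
#' @export
simulateSurvival <- function(cfg, mrna, truth) {
    prog <- truth$prognostic_genes
    if (!all(prog %in% rownames(mrna)))
        stop("prognostic genes missing from the expression matrix: ",
             paste(setdiff(prog, rownames(mrna)), collapse = ", "))
    withSeed(cfg@seed + 303L, {
        isCase <- groupOf(mrna) == "AD"
        if (!any(isCase)) stop("no case samples to generate survival for")
        cm <- countsOf(mrna)[prog, isCase, drop = FALSE]
        z <- t(apply(log2(cm + 1), 1, function(x) {
            s <- sd(x); if (s > 0) (x - mean(x)) / s else rep(0, length(x))
        }))
        lp <- as.numeric(crossprod(z, cfg@prognosticCoefs))
        n <- length(lp)
        rate <- cfg@baselineHazard * exp(lp)
        tEvent <- if (cfg@baselineHazard > 0) rexp(n, rate = rate)
                  else rep(Inf, n)
        cens <- if (cfg@censorHorizon > 0) runif(n, 0, cfg@censorHorizon)
                else rep(0, n)
        time <- pmin(tEvent, cens)
        event <- as.integer(tEvent <= cens)
        rz <- if (sd(lp) > 0) (lp - mean(lp)) / sd(lp) else rep(0, n)
        clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
        braaksc <- clamp(round(3 + 1.0 * rz + rnorm(n, sd = 0.8)), 0, 6)
        ceradsc <- clamp(round(2.5 + 0.6 * rz + rnorm(n, sd = 0.6)), 1, 4)
        dcfdx <- clamp(round(3.5 + 0.8 * rz + rnorm(n, sd = 0.8)), 1, 6)
        dataset <- rep("test", n)
        dataset[sample(n, round(0.4 * n))] <- "train"
        data.frame(sample = colnames(mrna)[isCase],
                   time_years = time, event = event,
                   braaksc = braaksc, ceradsc = ceradsc, dcfdx_lv = dcfdx,
                   dataset = dataset, stringsAsFactors = FALSE)
    })
}

#' Run the full generator
#'
#' Convenience wrapper chaining [simulatePathways()], [simulateCounts()]
#' and [simulateSurvival()]. Use [writeSimulation()] to materialise the
#' study as the pipeline's input files.
#'
#' @param cfg a [SimConfig-class].
#' @return list: `pathways`, `mrna`, `lnc`, `truth`, `survival`.
#' @examples
#' sim <- simulateCrosstalkStudy(simConfig(seed = 7))
#' sim$pathways
#' @export
simulateCrosstalkStudy <- function(cfg = simConfig()) {
    pw <- simulatePathways(cfg)
    cnt <- simulateCounts(cfg, pw)
    surv <- simulateSurvival(cfg, cnt$mrna, cnt$truth)
    list(pathways = pw, mrna = cnt$mrna, lnc = cnt$lnc,
         truth = cnt$truth, survival = surv)
}
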