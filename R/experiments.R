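## Seeded experiment drivers: reproducible desk-scale studies of the
## distance-scaling law, hurdle scarcity, the median phase change, the
## above-phase error, ball volumes, and the critical-constant report.
##
## Two clocks appear in the theory and both are exposed: the scaling and
## hurdle studies parameterise c via u = c*n/2 steps (the two-genome
## comparison clock), the phase studies via u = c*n/4 (the k-walk median
## clock), and the above-phase study supports u = c*n. Every table records
## u and n so no unit confusion is possible.

.experiment_rows <- function(rows) {
    df <- do.call(rbind, lapply(rows, as.data.frame))
    rownames(df) <- NULL
    df
}

#' Distance-scaling experiment
#'
#' For each `c` in the grid, runs replicate walks of `u = round(c n / 2)`
#' reversals and records both normalized distances against the prediction
#' `1 - f(c)`, plus the residuals scaled by `a_n sqrt(n)` (with
#' `a_n = log n` by default; any diverging sequence is admissible and the
#' choice only rescales a diagnostic column).
#'
#' @param n Number of genes.
#' @param cGrid Positive clock constants.
#' @param replicates Walks per grid point.
#' @param seed Master seed; per-replicate child seeds are recorded.
#' @param sampling Walk sampling mode, see [stepWalk()].
#' @param an Normalising sequence value (default `log(n)`).
#' @return data.frame with one row per (c, replicate) and a per-`c` means
#'   summary in `attr(, "summary")`.
#' @export
scalingExperiment <- function(n = 2000, cGrid = c(0.25, 0.5, 1, 2),
                              replicates = 20, seed = 1,
                              sampling = c("element_pairs",
                                           "positions_with_singletons"),
                              an = log(n)) {
    sampling <- match.arg(sampling)
    stopifnot(all(cGrid >= 0), replicates >= 1)
    seeds <- .child_seeds(seed, length(cGrid) * replicates)
    rows <- list()
    idx <- 0L
    for (c0 in cGrid) {
        u <- as.integer(round(c0 * n / 2))
        pred <- if (u == 0L) 0 else 1 - fValue(2 * u / n)
        for (r in seq_len(replicates)) {
            idx <- idx + 1L
            traj <- runWalk(n, steps = u, sampling = sampling,
                            seed = seeds[idx], record = FALSE)
            v <- .breakdown_vec(traj@endpoint@genes)
            rows[[idx]] <- list(
                c = c0, u = u, n = n, replicate = r, seed = seeds[idx],
                dcj = unname(v[["dcj"]]), reversal = unname(v[["reversal"]]),
                hurdles = unname(v[["hurdles"]]),
                fortress = unname(v[["fortress"]]),
                dcj_n = unname(v[["dcj"]]) / n,
                reversal_n = unname(v[["reversal"]]) / n,
                predicted = pred,
                resid_dcj = unname(v[["dcj"]]) / n - pred,
                resid_reversal = unname(v[["reversal"]]) / n - pred,
                resid_dcj_scaled = (unname(v[["dcj"]]) - pred * n) /
                    (an * sqrt(n)),
                resid_reversal_scaled = (unname(v[["reversal"]]) - pred * n) /
                    (an * sqrt(n)))
        }
    }
    df <- .experiment_rows(rows)
    sm <- do.call(rbind, lapply(split(df, df$c), function(d) {
        data.frame(c = d$c[1L], u = d$u[1L], predicted = d$predicted[1L],
                   mean_dcj_n = mean(d$dcj_n),
                   mean_reversal_n = mean(d$reversal_n),
                   mean_hurdles = mean(d$hurdles),
                   se_dcj_n = stats::sd(d$dcj_n) / sqrt(nrow(d)))
    }))
    rownames(sm) <- NULL
    attr(df, "summary") <- sm
    df
}

#' Hurdle-scarcity experiment
#'
#' Hurdle counts of walk endpoints after `u = round(c n / 2)` steps,
#' reported raw, per gene, and scaled by `a_n sqrt(n)` (the theory says
#' the count is negligible on that scale).
#'
#' @inheritParams scalingExperiment
#' @param c Clock constant (default 1, the half-time point).
#' @return data.frame, one row per replicate; means in
#'   `attr(, "summary")`.
#' @export
hurdleExperiment <- function(n = 2000, c = 1, replicates = 20, seed = 1,
                             sampling = c("element_pairs",
                                          "positions_with_singletons"),
                             an = log(n)) {
    sampling <- match.arg(sampling)
    u <- as.integer(round(c * n / 2))
    seeds <- .child_seeds(seed, replicates)
    rows <- lapply(seq_len(replicates), function(r) {
        traj <- runWalk(n, steps = u, sampling = sampling,
                        seed = seeds[r], record = FALSE)
        v <- .breakdown_vec(traj@endpoint@genes)
        list(c = c, u = u, n = n, replicate = r, seed = seeds[r],
             hurdles = unname(v[["hurdles"]]),
             fortress = unname(v[["fortress"]]),
             hurdles_n = unname(v[["hurdles"]]) / n,
             hurdles_scaled = unname(v[["hurdles"]]) / (an * sqrt(n)),
             dcj = unname(v[["dcj"]]), reversal = unname(v[["reversal"]]))
    })
    df <- .experiment_rows(rows)
    attr(df, "summary") <- data.frame(
        c = c, u = u, n = n,
        mean_hurdles = mean(df$hurdles),
        mean_hurdles_n = mean(df$hurdles_n),
        mean_hurdles_scaled = mean(df$hurdles_scaled),
        fortress_rate = mean(df$fortress))
    df
}

## per-replicate median bookkeeping shared by the phase drivers
.phase_replicate <- function(n, k, u, metric, sampling, childSeed,
                             solveExact) {
    gs <- runEnsemble(k, n, steps = u, sampling = sampling,
                      seed = childSeed, record = FALSE)
    eps <- endpoints(gs)
    g_id <- sum(vapply(eps, function(x) .dist_vec(x@genes, metric),
                       integer(1L)))
    s <- 0L
    for (i in seq_len(k - 1L))
        for (j in (i + 1L):k)
            s <- s + .dist_vec(.relabel_vec(eps[[i]]@genes, eps[[j]]@genes),
                               metric)
    lb <- as.integer(ceiling(s / (k - 1L)))
    ubr <- inputUpperBound(eps, metric)
    ub <- ubr$value
    cert <- ub <= lb
    m <- NA_real_
    if (cert) {
        m <- as.numeric(ub)
    } else if (solveExact && n <= 6L) {
        m <- medianValue(medianExact(eps, metric = metric,
                                     mode = "exhaustive"))
    }
    list(g_id = g_id, pairsum = s, lower = lb, upper = ub,
         certificate = cert, m = m)
}

#' Median phase-change experiment (below and around n/4)
#'
#' For each step count `u` (or `u = round(c n / 4)` from `cGrid`), runs
#' replicate ensembles of `k` walks and records the total distance of the
#' identity `g_id`, the perimeter lower bound, the evaluate-the-inputs
#' upper bound, whether they certify the median value, the certified (or,
#' at `n <= 6`, exhaustively solved) value `m`, the recovery statistic
#' `m / (k u)` and the error bounds on `epsilon = g_id - m`. Below the
#' phase the certificate typically proves `m = k u` — the median value
#' recovers k times the divergence time.
#'
#' @inheritParams scalingExperiment
#' @param k Walks per ensemble.
#' @param u Integer step counts (one experiment row group per value).
#' @param cGrid Alternative to `u`: clock constants with
#'   `u = round(c n / 4)`.
#' @param metric `"dcj"` or `"reversal"`.
#' @return data.frame, one row per (u, replicate); per-`u` summary
#'   (certificate success fraction, mean `m`) in `attr(, "summary")`.
#' @export
phaseExperiment <- function(n = 100, k = 3, u = NULL, cGrid = NULL,
                            replicates = 20, seed = 1,
                            metric = c("dcj", "reversal"),
                            sampling = c("element_pairs",
                                         "positions_with_singletons")) {
    metric <- match.arg(metric)
    sampling <- match.arg(sampling)
    if (is.null(u)) {
        if (is.null(cGrid)) stop("give u or cGrid")
        u <- as.integer(round(cGrid * n / 4))
    }
    u <- as.integer(u)
    seeds <- .child_seeds(seed, length(u) * replicates)
    rows <- list()
    idx <- 0L
    for (ui in u) {
        for (r in seq_len(replicates)) {
            idx <- idx + 1L
            pr <- .phase_replicate(n, k, ui, metric, sampling, seeds[idx],
                                   solveExact = TRUE)
            rows[[idx]] <- list(
                u = ui, n = n, k = k, replicate = r, seed = seeds[idx],
                g_id = pr$g_id, pairsum = pr$pairsum,
                lower = pr$lower, upper = pr$upper,
                certificate = pr$certificate, m = pr$m,
                recovery = if (!is.na(pr$m) && ui > 0L) pr$m / (k * ui)
                           else NA_real_,
                eps_lower = pr$g_id - pr$upper,
                eps_upper = pr$g_id - pr$lower)
        }
    }
    df <- .experiment_rows(rows)
    sm <- do.call(rbind, lapply(split(df, df$u), function(d) {
        data.frame(u = d$u[1L], n = n, k = k,
                   certificate_rate = mean(d$certificate),
                   solved_rate = mean(!is.na(d$m)),
                   mean_m = mean(d$m, na.rm = TRUE),
                   mean_g_id = mean(d$g_id))
    }))
    rownames(sm) <- NULL
    sm <- sm[order(sm$u), , drop = FALSE]
    attr(df, "summary") <- sm
    df
}

#' Above-phase separation experiment
#'
#' Deep in the saturated regime the identity is provably far from optimal:
#' the evaluate-the-inputs upper bound (an input genome reaches the other
#' two in about two saturated distances, against three for the identity)
#' certifies `epsilon = g_id - m >= g_id - min_x g(x)` of order `n`. When
#' `u > n/2` the table also reports the predicted error rate
#' `alpha = k (1 - f(2u/n))`.
#'
#' @inheritParams phaseExperiment
#' @return data.frame, one row per replicate group; summary in
#'   `attr(, "summary")`.
#' @export
abovePhaseExperiment <- function(n = 500, k = 3, u = 1500, replicates = 10,
                                 seed = 1, metric = c("dcj", "reversal"),
                                 sampling = c("element_pairs",
                                              "positions_with_singletons")) {
    metric <- match.arg(metric)
    sampling <- match.arg(sampling)
    u <- as.integer(u)
    seeds <- .child_seeds(seed, length(u) * replicates)
    rows <- list()
    idx <- 0L
    for (ui in u) {
        cc <- ui / n
        alpha <- if (cc > 1 / 2) alphaC(cc, k) else NA_real_
        for (r in seq_len(replicates)) {
            idx <- idx + 1L
            pr <- .phase_replicate(n, k, ui, metric, sampling, seeds[idx],
                                   solveExact = FALSE)
            rows[[idx]] <- list(
                u = ui, n = n, k = k, replicate = r, seed = seeds[idx],
                g_id = pr$g_id, upper = pr$upper,
                eps_lb = pr$g_id - pr$upper,
                eps_lb_n = (pr$g_id - pr$upper) / n,
                kcn_minus_m_lb = k * ui - pr$upper,
                kcn_minus_m_lb_n = (k * ui - pr$upper) / n,
                alpha = alpha)
        }
    }
    df <- .experiment_rows(rows)
    sm <- do.call(rbind, lapply(split(df, df$u), function(d) {
        data.frame(u = d$u[1L], n = n, k = k,
                   mean_eps_lb_n = mean(d$eps_lb_n),
                   mean_kcn_minus_m_lb_n = mean(d$kcn_minus_m_lb_n),
                   alpha = d$alpha[1L])
    }))
    rownames(sm) <- NULL
    attr(df, "summary") <- sm
    df
}

#' Ball-volume experiment
#'
#' Monte-Carlo estimate of the normalized volume of the radius-`c n` ball
#' around the identity: the fraction of uniformly random signed
#' permutations whose DCJ (resp. reversal) distance to the identity is at
#' most `c n`. Also reports the mean cycles-per-gene of the random
#' genomes (which shrinks like `log(n)/n`, explaining why random genomes
#' sit at nearly maximal distance and the ball volume vanishes).
#'
#' @param n Number of genes.
#' @param c Radius constant in `(0, 1)`.
#' @param draws Number of uniform draws.
#' @param seed Master seed.
#' @return One-row data.frame with the two volume estimates (the
#'   reversal-ball estimate can never exceed the DCJ one: the reversal
#'   ball is nested inside the DCJ ball) and the mean cycle fraction.
#' @export
ballVolumeExperiment <- function(n = 300, c = 0.8, draws = 2000, seed = 1) {
    stopifnot(c > 0, c < 1, draws >= 1)
    radius <- c * n
    set.seed(seed)
    hits_dcj <- 0L
    hits_rev <- 0L
    cyc <- numeric(draws)
    for (i in seq_len(draws)) {
        g <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
        bp <- .bp_build(g)
        cyc[i] <- bp$ncyc
        ddcj <- n + 1L - bp$ncyc
        if (ddcj <= radius) {
            hits_dcj <- hits_dcj + 1L
            hf <- .hp_counts(bp)
            if (ddcj + hf[1L] + hf[2L] <= radius) hits_rev <- hits_rev + 1L
        }
    }
    data.frame(n = n, c = c, draws = draws, seed = seed,
               hits_dcj = hits_dcj, hits_reversal = hits_rev,
               gamma_dcj = hits_dcj / draws,
               gamma_reversal = hits_rev / draws,
               mean_cycles = mean(cyc),
               mean_cycles_n = mean(cyc) / n)
}

#' Critical-constant report
#'
#' Solves `f(x/2) = 1/3` and prints the root with its residual and the
#' consistency bounds `2 < c* <= 3`.
#'
#' @param bracket,xtol Passed to [solveCStar()].
#' @return Invisibly, a list with the [PhaseSummary-class] and the two
#'   bound checks.
#' @export
cStarReport <- function(bracket = c(0.5, 9), xtol = 1e-6) {
    ps <- solveCStar(bracket = bracket, xtol = xtol)
    show(ps)
    okLow <- ps@cStar > 2
    okHigh <- ps@cStar <= 3
    cat(sprintf("  consistency: c* > 2 %s; c* <= 3 %s\n",
                if (okLow) "OK" else "FAILED",
                if (okHigh) "OK" else "FAILED"))
    invisible(list(summary = ps, above2 = okLow, atMost3 = okHigh))
}

#' Write an experiment table as CSV with a summary block
#'
#' The replicate rows are written as a plain CSV (header + one record per
#' replicate); the summary rows follow, each line prefixed with
#' `#summary,`.
#'
#' @param df An experiment data.frame (with optional
#'   `attr(, "summary")`).
#' @param file Path or connection.
#' @return Invisibly, `df`.
#' @export
writeResultTable <- function(df, file) {
    con <- if (is.character(file)) file(file, "w") else file
    if (is.character(file)) on.exit(close(con))
    utils::write.csv(df, con, row.names = FALSE)
    sm <- attr(df, "summary")
    if (!is.null(sm)) {
        txt <- utils::capture.output(
            utils::write.csv(sm, stdout(), row.names = FALSE))
        writeLines(paste0("#summary,", txt), con)
    }
    invisible(df)
}
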