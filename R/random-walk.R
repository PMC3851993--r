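## The reversal random walk: from the identity, apply uniformly random
## reversals, either a fixed number of steps or a Poisson(t) number
## (global rate-1 clock, so time t corresponds to ~t reversals).

## one sampling step on raw state; `state` is list(perm, pos) where
## pos[|gene|] is the gene's current slot
.walk_step <- function(state, n, sampling) {
    if (sampling == "element_pairs") {
        ij <- sample.int(n, 2L)
        pa <- state$pos[ij[1L]]
        pb <- state$pos[ij[2L]]
        if (pa > pb) { tmp <- pa; pa <- pb; pb <- tmp }
    } else {
        ## unordered pair of the n+1 black-edge gaps 0..n; gaps (g1, g2)
        ## with g1 < g2 reverse positions g1+1 .. g2 (singletons included)
        gp <- sample.int(n + 1L, 2L) - 1L
        pa <- min(gp) + 1L
        pb <- max(gp)
    }
    seg <- pa:pb
    state$perm[seg] <- -rev(state$perm[seg])
    state$pos[abs(state$perm[seg])] <- seg
    state$op <- c(pa, pb)
    state
}

#' One step of the reversal random walk
#'
#' Default sampling draws an unordered pair of distinct gene labels
#' uniformly from the `choose(n, 2)` pairs and reverses the inclusive
#' segment between their current positions. The alternative
#' `"positions_with_singletons"` draws a pair of the `n + 1` black-edge
#' gaps (`choose(n + 1, 2)` choices), which includes one-gene sign flips.
#'
#' @param x A [SignedPermutation-class] (`n >= 2` under the default
#'   sampling).
#' @param sampling Sampling mode.
#' @return List with `state` (the new [SignedPermutation-class]) and `op`
#'   (the applied [ReversalOp-class], positions mode, for replay).
#' @export
stepWalk <- function(x, sampling = c("element_pairs",
                                     "positions_with_singletons")) {
    stopifnot(is(x, "SignedPermutation"))
    sampling <- match.arg(sampling)
    n <- length(x@genes)
    if (sampling == "element_pairs" && n < 2L)
        stop("element-pair sampling needs n >= 2")
    st <- list(perm = x@genes, pos = .slot_positions(x@genes))
    st <- .walk_step(st, n, sampling)
    list(state = new("SignedPermutation", genes = st$perm),
         op = ReversalOp(st$op[1L], st$op[2L]))
}

.slot_positions <- function(genes) {
    pos <- integer(length(genes))
    pos[abs(genes)] <- seq_along(genes)
    pos
}

#' Run a reversal random walk
#'
#' Starts at the identity and applies random reversals. Either `steps`
#' (fixed step count) or `time` (the step count is drawn from a Poisson law
#' with mean `time`; rate-1 clock) must be given. Fully deterministic given
#' `seed`.
#'
#' @param n Number of genes (`>= 2` under the default sampling).
#' @param steps Nonnegative integer number of reversals.
#' @param time Nonnegative Poisson mean, alternative to `steps`.
#' @param sampling See [stepWalk()].
#' @param seed Optional integer seed.
#' @param record Keep the applied operations for replay (default `TRUE`).
#' @return A [WalkTrajectory-class].
#' @examples
#' traj <- runWalk(20, steps = 5, seed = 1)
#' dcjDistance(walkEndpoint(traj))
#' @export
runWalk <- function(n, steps = NULL, time = NULL,
                    sampling = c("element_pairs",
                                 "positions_with_singletons"),
                    seed = NULL, record = TRUE) {
    sampling <- match.arg(sampling)
    n <- as.integer(n)
    if (n < 1L) stop("n must be positive")
    if (sampling == "element_pairs" && n < 2L)
        stop("element-pair sampling needs n >= 2")
    if (is.null(steps) == is.null(time))
        stop("give exactly one of 'steps' or 'time'")
    if (!is.null(seed)) set.seed(seed)
    schedule <- if (is.null(time)) "fixed_steps" else "poisson_time"
    if (!is.null(time)) {
        if (time < 0) stop("time must be >= 0")
        steps <- stats::rpois(1L, time)
    }
    steps <- as.integer(steps)
    if (is.na(steps) || steps < 0L) stop("steps must be >= 0")
    st <- list(perm = seq_len(n), pos = seq_len(n))
    ops <- matrix(0L, nrow = 2L, ncol = if (record) steps else 0L)
    for (s in seq_len(steps)) {
        st <- .walk_step(st, n, sampling)
        if (record) ops[, s] <- st$op
    }
    new("WalkTrajectory", n = n, ops = ops, sampling = sampling,
        schedule = schedule,
        time = if (is.null(time)) NA_real_ else as.numeric(time),
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        endpoint = new("SignedPermutation", genes = st$perm))
}

#' Endpoint of a walk
#'
#' @param traj A [WalkTrajectory-class].
#' @return The final [SignedPermutation-class].
#' @export
walkEndpoint <- function(traj) {
    stopifnot(is(traj, "WalkTrajectory"))
    traj@endpoint
}

#' Number of steps a trajectory applied
#'
#' @param traj A [WalkTrajectory-class].
#' @return Integer step count.
#' @export
walkSteps <- function(traj) {
    stopifnot(is(traj, "WalkTrajectory"))
    ncol(traj@ops)
}

#' Replay a trajectory's recorded operations from the identity
#'
#' @param traj A [WalkTrajectory-class] recorded with `record = TRUE`.
#' @param upto Replay only the first `upto` steps (default: all).
#' @return The [SignedPermutation-class] after `upto` steps.
#' @export
replayTrajectory <- function(traj, upto = ncol(traj@ops)) {
    stopifnot(is(traj, "WalkTrajectory"))
    upto <- as.integer(upto)
    if (upto < 0L || upto > ncol(traj@ops))
        stop("upto out of range")
    g <- seq_len(traj@n)
    for (s in seq_len(upto))
        g <- .reverse_segment(g, traj@ops[1L, s], traj@ops[2L, s])
    new("SignedPermutation", genes = g)
}

#' @describeIn numGenes gene count of a trajectory
#' @export
setMethod("numGenes", "WalkTrajectory", function(x) x@n)

setMethod("show", "WalkTrajectory", function(object) {
    cat(sprintf(
        "WalkTrajectory: n = %d, %d step(s), %s schedule, %s sampling\n",
        object@n, ncol(object@ops), object@schedule, object@sampling))
})

## child seeds: drawn from a stream seeded by the master seed
.child_seeds <- function(seed, m) {
    if (is.null(seed) || is.na(seed)) return(rep(NA_integer_, m))
    set.seed(seed)
    sample.int(2147483646L, m)
}

#' Run an ensemble of independent reversal walks
#'
#' `k` walks, all from the identity, each driven by a child seed derived
#' deterministically from the master seed (see [GenomeSet-class]).
#'
#' @param k Number of walks (`>= 1`).
#' @inheritParams runWalk
#' @return A [GenomeSet-class].
#' @examples
#' gs <- runEnsemble(3, n = 50, steps = 5, seed = 1)
#' vapply(endpoints(gs), dcjDistance, integer(1))
#' @export
runEnsemble <- function(k, n, steps = NULL, time = NULL,
                        sampling = c("element_pairs",
                                     "positions_with_singletons"),
                        seed = NULL, record = TRUE) {
    sampling <- match.arg(sampling)
    k <- as.integer(k)
    if (k < 1L) stop("k must be >= 1")
    seeds <- .child_seeds(seed, k)
    walks <- lapply(seq_len(k), function(i) {
        runWalk(n, steps = steps, time = time, sampling = sampling,
                seed = if (is.na(seeds[i])) NULL else seeds[i],
                record = record)
    })
    new("GenomeSet", n = as.integer(n), k = k, walks = walks,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @describeIn endpoints endpoints of an ensemble
#' @export
setMethod("endpoints", "GenomeSet", function(x) {
    stats::setNames(lapply(x@walks, walkEndpoint),
                    paste0("walk", seq_len(x@k)))
})

#' @describeIn numGenes gene count of an ensemble
#' @export
setMethod("numGenes", "GenomeSet", function(x) x@n)

setMethod("show", "GenomeSet", function(object) {
    cat(sprintf("GenomeSet: k = %d independent walks on n = %d genes\n",
                object@k, object@n))
})

#' Distance profile of a trajectory
#'
#' Replays the recorded operations and reports the distance to the
#' identity at the requested step checkpoints.
#'
#' @param traj A [WalkTrajectory-class] with recorded operations.
#' @param metric `"dcj"` or `"reversal"`.
#' @param at Integer vector of checkpoint steps within `[0, steps]`.
#' @return data.frame with columns `step` and `distance`.
#' @export
distanceProfile <- function(traj, metric = c("dcj", "reversal"),
                            at = seq(0L, ncol(traj@ops))) {
    stopifnot(is(traj, "WalkTrajectory"))
    metric <- match.arg(metric)
    at <- sort(unique(as.integer(at)))
    u <- ncol(traj@ops)
    if (any(at < 0L) || any(at > u))
        stop(sprintf("checkpoints must lie in [0, %d]", u))
    g <- seq_len(traj@n)
    out <- integer(length(at))
    cur <- 0L
    for (i in seq_along(at)) {
        while (cur < at[i]) {
            cur <- cur + 1L
            g <- .reverse_segment(g, traj@ops[1L, cur], traj@ops[2L, cur])
        }
        out[i] <- .dist_vec(g, metric)
    }
    data.frame(step = at, distance = out)
}
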