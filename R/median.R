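## The median value m(A) = min_x sum_{y in A} d(x, y): total-distance
## evaluation, the triangle-inequality (perimeter) lower bound, the
## evaluate-the-inputs upper bound, and exact solvers (exhaustive
## enumeration and best-first branch-and-bound) for small n. The
## lower == upper certificate is what makes below-phase experiments at
## n = 100+ feasible, where enumeration is impossible.

.mw_cache <- new.env(parent = emptyenv())

## genomes argument: a GenomeSet or a (possibly named) list of
## SignedPermutation objects
.as_genome_list <- function(genomes) {
    if (is(genomes, "GenomeSet")) genomes <- endpoints(genomes)
    if (is(genomes, "SignedPermutation")) genomes <- list(genomes)
    if (!is.list(genomes) || length(genomes) == 0L ||
        !all(vapply(genomes, is, logical(1L), "SignedPermutation")))
        stop("genomes must be a GenomeSet or a list of SignedPermutation")
    n <- unique(vapply(genomes, function(g) length(g@genes), integer(1L)))
    if (length(n) != 1L)
        stop("all genomes must share the same number of genes")
    genomes
}

## distance-to-identity lookup table over the whole group (cached)
.dist_table <- function(n, metric) {
    key <- paste0("tab_", metric, "_", n)
    if (!is.null(.mw_cache[[key]])) return(.mw_cache[[key]])
    M <- enumerateSignedPermutations(n)
    d <- integer(nrow(M))
    for (i in seq_len(nrow(M))) d[i] <- .dist_vec(M[i, ], metric)
    tab <- stats::setNames(d, .row_keys(M))
    .mw_cache[[key]] <- list(M = M, tab = tab)
    .mw_cache[[key]]
}

## total distance of every row of state matrix M to the genome list
.g_rows <- function(M, ylist, metric, tab = NULL) {
    g <- numeric(nrow(M))
    for (y in ylist) {
        R <- .relabel_rows(M, y@genes)
        if (!is.null(tab)) {
            g <- g + unname(tab[.row_keys(R)])
        } else {
            for (i in seq_len(nrow(R))) g[i] <- g[i] + .dist_vec(R[i, ], metric)
        }
    }
    g
}

#' Total distance from a candidate genome to a genome set
#'
#' `g_A(x) = sum_{y in A} d(x, y)` under the chosen metric.
#'
#' @param x A [SignedPermutation-class] candidate.
#' @param genomes A [GenomeSet-class] or list of
#'   [SignedPermutation-class] objects.
#' @param metric `"dcj"` or `"reversal"`.
#' @return Nonnegative integer.
#' @export
totalDistance <- function(x, genomes, metric = c("dcj", "reversal")) {
    metric <- match.arg(metric)
    stopifnot(is(x, "SignedPermutation"))
    ylist <- .as_genome_list(genomes)
    if (length(ylist[[1L]]@genes) != length(x@genes))
        stop("candidate and genomes must share the same number of genes")
    sum(vapply(ylist, function(y)
        .dist_vec(.relabel_vec(x@genes, y@genes), metric), integer(1L)))
}

#' Perimeter lower bound on the median value
#'
#' The triangle inequality summed over unordered pairs gives
#' `sum_{i<j} d(X_i, X_j) <= (k - 1) m(A)`; the bound is the ceiling of
#' the pairwise sum divided by `k - 1`. Never exceeds the true median
#' value.
#'
#' @inheritParams totalDistance
#' @return Nonnegative integer (0 when `k < 2`).
#' @export
perimeterLowerBound <- function(genomes, metric = c("dcj", "reversal")) {
    metric <- match.arg(metric)
    ylist <- .as_genome_list(genomes)
    k <- length(ylist)
    if (k < 2L) return(0L)
    s <- 0L
    for (i in seq_len(k - 1L))
        for (j in (i + 1L):k)
            s <- s + .dist_vec(
                .relabel_vec(ylist[[i]]@genes, ylist[[j]]@genes), metric)
    as.integer(ceiling(s / (k - 1L)))
}

#' Evaluate-the-inputs upper bound on the median value
#'
#' Evaluates `g_A` at every input genome and at the identity and returns
#' the best: a valid upper bound with a witness. Above the phase the
#' winning witness is typically an input genome rather than the identity
#' (its total distance is about `(k-1)` saturated distances instead of
#' `k`).
#'
#' @inheritParams totalDistance
#' @return List with `value` and `witness` (a
#'   [SignedPermutation-class]). Ties keep the first candidate in input
#'   order (the identity is evaluated last).
#' @export
inputUpperBound <- function(genomes, metric = c("dcj", "reversal")) {
    metric <- match.arg(metric)
    ylist <- .as_genome_list(genomes)
    n <- length(ylist[[1L]]@genes)
    cands <- c(ylist, list(identityPermutation(n)))
    vals <- vapply(cands, function(x)
        totalDistance(x, ylist, metric = metric), numeric(1L))
    best <- which.min(vals)
    list(value = as.integer(vals[best]), witness = cands[[best]])
}

## canonical-order comparison helpers (-n < ... < -1 < +1 < ... < +n)
.canonical_first <- function(M, n) {
    R <- .canonical_ranks(M, n)
    do.call(order, as.data.frame(R))[1L]
}

.canonical_less <- function(a, b, n) {
    ra <- .canonical_ranks(matrix(a, 1L), n)
    rb <- .canonical_ranks(matrix(b, 1L), n)
    d <- ra - rb
    nz <- which(d != 0L)
    length(nz) > 0L && d[nz[1L]] < 0L
}

#' Exact median value of a genome set
#'
#' First computes the perimeter lower bound and the evaluate-the-inputs
#' upper bound; if they agree the result is certified without any search.
#' Otherwise the exhaustive path enumerates the whole group (`n <= 6`) and
#' the branch-and-bound path runs a best-first search over the reversal
#' graph, seeded at the upper-bound witness, the inputs and the identity,
#' expanding lowest-`g` nodes first. The search closes (proves exactness)
#' when the incumbent meets the perimeter bound or the whole space has
#' been visited; if the node budget runs out first, the result is an
#' explicitly flagged open interval, never a silent approximation.
#'
#' Witness tie-break: the reported witness is the first optimum in
#' canonical order on signed sequences (`-n < ... < -1 < +1 < ... < +n`,
#' slot by slot).
#'
#' @inheritParams totalDistance
#' @param mode `"auto"` (exhaustive for `n <= 6`, else branch-and-bound),
#'   `"exhaustive"`, or `"bnb"`.
#' @param budget Node-expansion limit for branch-and-bound.
#' @return A [MedianResult-class].
#' @examples
#' p <- SignedPermutation(c(-2L, 1L, 3L))
#' medianExact(list(identityPermutation(3), p, p))
#' @export
medianExact <- function(genomes, metric = c("dcj", "reversal"),
                        mode = c("auto", "exhaustive", "bnb"),
                        budget = 2e5) {
    metric <- match.arg(metric)
    mode <- match.arg(mode)
    ylist <- .as_genome_list(genomes)
    n <- length(ylist[[1L]]@genes)
    lb <- perimeterLowerBound(ylist, metric)
    ub <- inputUpperBound(ylist, metric)
    if (ub$value <= lb) {
        return(new("MedianResult", value = as.numeric(ub$value),
                   lower = as.numeric(ub$value),
                   upper = as.numeric(ub$value),
                   witness = ub$witness, method = "certificate",
                   nodes = length(ylist) + 1, closed = TRUE))
    }
    if (mode == "auto") mode <- if (n <= 6L) "exhaustive" else "bnb"
    if (mode == "exhaustive") {
        if (n > 6L)
            stop("exhaustive median search is limited to n <= 6")
        dt <- .dist_table(n, metric)
        g <- .g_rows(dt$M, ylist, metric, tab = dt$tab)
        m <- min(g)
        opt <- dt$M[g == m, , drop = FALSE]
        w <- opt[.canonical_first(opt, n), ]
        return(new("MedianResult", value = as.numeric(m),
                   lower = as.numeric(m), upper = as.numeric(m),
                   witness = new("SignedPermutation", genes = as.integer(w)),
                   method = "exhaustive", nodes = nrow(dt$M),
                   closed = TRUE))
    }
    .median_bnb(ylist, metric, lb, ub, budget)
}

.median_bnb <- function(ylist, metric, lb, ub, budget) {
    n <- length(ylist[[1L]]@genes)
    tab <- if (n <= 6L) .dist_table(n, metric)$tab else NULL
    totalStates <- if (n <= 12L) 2^n * factorial(n) else Inf
    ops <- .all_reversal_ops(n)
    nops <- ncol(ops)

    visited <- new.env(parent = emptyenv())
    gmax <- length(ylist) * (n + 1L)
    buckets <- vector("list", gmax + 1L)   # bucket g+1 holds states with value g
    nvisited <- 0L

    incumbent <- ub$value
    witness <- ub$witness@genes

    add_states <- function(M) {
        keys <- .row_keys(M)
        fresh <- !vapply(keys, function(k) !is.null(visited[[k]]),
                         logical(1L))
        if (!any(fresh)) return(invisible())
        M <- M[fresh, , drop = FALSE]
        keys <- keys[fresh]
        g <- .g_rows(M, ylist, metric, tab = tab)
        for (i in seq_along(keys)) {
            visited[[keys[i]]] <- TRUE
            nvisited <<- nvisited + 1L
            gi <- g[i]
            if (gi < incumbent ||
                (gi == incumbent && .canonical_less(M[i, ], witness, n))) {
                incumbent <<- as.integer(gi)
                witness <<- M[i, ]
            }
            b <- gi + 1L
            buckets[[b]] <<- c(buckets[[b]], list(M[i, ]))
        }
        invisible()
    }

    seeds <- unique(lapply(c(ylist, list(identityPermutation(n))),
                           function(x) x@genes))
    add_states(do.call(rbind, seeds))

    nodes <- 0L
    while (incumbent > lb && nodes < budget && nvisited < totalStates) {
        b <- which(lengths(buckets) > 0L)
        if (length(b) == 0L) break
        b <- b[1L]
        st <- buckets[[b]][[1L]]
        buckets[[b]][[1L]] <- NULL
        nodes <- nodes + 1L
        ## all single-reversal neighbours
        Mn <- matrix(rep(st, each = nops), nrow = nops)
        for (j in seq_len(nops)) {
            a <- ops[1L, j]; bb <- ops[2L, j]
            Mn[j, a:bb] <- -rev(st[a:bb])
        }
        add_states(Mn)
    }

    closed <- incumbent <= lb || nvisited >= totalStates
    new("MedianResult",
        value = if (closed) as.numeric(incumbent) else NA_real_,
        lower = if (closed) as.numeric(incumbent) else as.numeric(lb),
        upper = as.numeric(incumbent),
        witness = new("SignedPermutation", genes = as.integer(witness)),
        method = "branch_bound", nodes = nodes, closed = closed)
}

setMethod("show", "MedianResult", function(object) {
    if (object@closed) {
        cat(sprintf("MedianResult: m = %g (%s, %g nodes)\n",
                    object@value, object@method, object@nodes))
    } else {
        cat(sprintf(
            "MedianResult: open interval [%g, %g] (%s, budget exhausted after %g nodes)\n",
            object@lower, object@upper, object@method, object@nodes))
    }
    cat("  witness:", paste(sprintf("%+d", object@witness@genes),
                            collapse = " "), "\n")
})

#' Median accessors
#'
#' @param x A [MedianResult-class].
#' @return `medianValue`: the exact value (`NA` when not closed);
#'   `medianBounds`: `c(lower, upper)`; `medianWitness`: the witness
#'   genome; `isClosed`: logical.
#' @name median-accessors
NULL

#' @rdname median-accessors
#' @export
medianValue <- function(x) { stopifnot(is(x, "MedianResult")); x@value }

#' @rdname median-accessors
#' @export
medianBounds <- function(x) {
    stopifnot(is(x, "MedianResult")); c(lower = x@lower, upper = x@upper)
}

#' @rdname median-accessors
#' @export
medianWitness <- function(x) { stopifnot(is(x, "MedianResult")); x@witness }

#' @rdname median-accessors
#' @export
isClosed <- function(x) { stopifnot(is(x, "MedianResult")); x@closed }

#' Error of the identity as a median estimate
#'
#' For walk ensembles started at the identity,
#' `epsilon = g_A(id) - m(A) >= 0` measures how far the ancestor is from
#' being a median solution. When the solver cannot close, `epsilon` is
#' reported as the certified interval
#' `[g_id - upper, g_id - lower]`.
#'
#' @inheritParams medianExact
#' @return List with `g_id`, `median` (a [MedianResult-class]) and
#'   `epsilon` (single value when closed, else `c(lower, upper)`).
#' @export
epsilonValue <- function(genomes, metric = c("dcj", "reversal"),
                         mode = c("auto", "exhaustive", "bnb"),
                         budget = 2e5) {
    metric <- match.arg(metric)
    mode <- match.arg(mode)
    ylist <- .as_genome_list(genomes)
    n <- length(ylist[[1L]]@genes)
    g_id <- totalDistance(identityPermutation(n), ylist, metric)
    med <- medianExact(ylist, metric = metric, mode = mode, budget = budget)
    eps <- if (med@closed) g_id - med@value
           else c(lower = g_id - med@upper, upper = g_id - med@lower)
    list(g_id = g_id, median = med, epsilon = eps)
}
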