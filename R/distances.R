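## DCJ and reversal distances assembled from breakpoint-graph statistics,
## plus a brute-force BFS oracle on the reversal Cayley graph for small n.

## fast internal: breakdown of `genes` against the identity
.breakdown_vec <- function(genes, needHurdles = TRUE) {
    bp <- .bp_build(genes)
    n <- bp$n
    dcj <- n + 1L - bp$ncyc
    if (needHurdles) {
        hf <- .hp_counts(bp)
    } else {
        hf <- c(0L, 0L)
    }
    c(n = n, cycles = bp$ncyc, hurdles = hf[1L], fortress = hf[2L],
      dcj = dcj, reversal = dcj + hf[1L] + hf[2L])
}

#' Distance breakdown for a genome pair
#'
#' Builds the breakpoint graph of the pair (via [relabel()] when `q` is
#' given) and assembles both distances from it: DCJ distance
#' `n + 1 - cycles` and reversal distance
#' `n + 1 - cycles + hurdles + fortress`.
#'
#' @param p A [SignedPermutation-class].
#' @param q Optional second genome (default: identity).
#' @return A [DistanceBreakdown-class].
#' @examples
#' distanceBreakdown(SignedPermutation(c(-1L)))        # one sign flip away
#' distanceBreakdown(SignedPermutation(c(3L, 2L, 1L))) # a hurdle: d_r = 3
#' @export
distanceBreakdown <- function(p, q = NULL) {
    stopifnot(is(p, "SignedPermutation"))
    g <- p@genes
    if (!is.null(q)) {
        stopifnot(is(q, "SignedPermutation"))
        if (length(q@genes) != length(g))
            stop("p and q must have the same number of genes")
        g <- .relabel_vec(g, q@genes)
    }
    v <- .breakdown_vec(g)
    new("DistanceBreakdown", n = v[["n"]], cycles = v[["cycles"]],
        hurdles = v[["hurdles"]], fortress = v[["fortress"]],
        dcj = v[["dcj"]], reversal = v[["reversal"]])
}

#' @describeIn dcjDistance from a precomputed breakdown
#' @export
setMethod("dcjDistance", c("DistanceBreakdown", "missing"),
    function(x, y) x@dcj)

#' @describeIn dcjDistance between two genomes (or one genome and the
#'   identity)
#' @export
setMethod("dcjDistance", c("SignedPermutation", "ANY"),
    function(x, y) {
        g <- x@genes
        if (!missing(y) && !is.null(y)) {
            stopifnot(is(y, "SignedPermutation"))
            g <- .relabel_vec(g, y@genes)
        }
        bp <- .bp_build(g)
        bp$n + 1L - bp$ncyc
    })

#' @describeIn reversalDistance from a precomputed breakdown
#' @export
setMethod("reversalDistance", c("DistanceBreakdown", "missing"),
    function(x, y) x@reversal)

#' @describeIn reversalDistance between two genomes (or one genome and the
#'   identity)
#' @export
setMethod("reversalDistance", c("SignedPermutation", "ANY"),
    function(x, y) {
        g <- x@genes
        if (!missing(y) && !is.null(y)) {
            stopifnot(is(y, "SignedPermutation"))
            g <- .relabel_vec(g, y@genes)
        }
        v <- .breakdown_vec(g)
        unname(v[["reversal"]])
    })

#' @describeIn numGenes gene count of a distance breakdown
#' @export
setMethod("numGenes", "DistanceBreakdown", function(x) x@n)

setMethod("show", "DistanceBreakdown", function(object) {
    cat(sprintf(
        "DistanceBreakdown (n = %d): cycles = %d, hurdles = %d, fortress = %d\n",
        object@n, object@cycles, object@hurdles, object@fortress))
    cat(sprintf("  dcj = %d, reversal = %d\n", object@dcj, object@reversal))
})

## internal fast path: distance of raw vector against the identity
.dist_vec <- function(genes, metric) {
    if (metric == "dcj") {
        bp <- .bp_build(genes)
        bp$n + 1L - bp$ncyc
    } else {
        unname(.breakdown_vec(genes)[["reversal"]])
    }
}

## all inclusive-segment reversals for n slots (singletons included),
## as a 2-row matrix of (a, b) position bounds
.all_reversal_ops <- function(n) {
    a <- rep(seq_len(n), times = n - seq_len(n) + 1L)
    b <- unlist(lapply(seq_len(n), function(i) i:n))
    rbind(a, b)
}

#' Exact reversal distances from the identity by breadth-first search
#'
#' Explores the Cayley graph of the signed symmetric group under all
#' inclusive-segment reversals (singleton sign flips included),
#' frontier-by-frontier from the identity, and returns the exact graph
#' distance of every state. Independent of the breakpoint-graph machinery;
#' used as the ground-truth oracle in validation.
#'
#' @param n Number of genes; `n <= 7` (the state space `2^n n!` must fit).
#' @return Named integer vector: distance per state, keyed by the
#'   space-separated signed gene order.
#' @export
bfsDistanceTable <- function(n) {
    n <- as.integer(n)
    if (n < 1L || n > 7L)
        stop("BFS oracle is limited to n <= 7 (state space 2^n * n!)")
    ops <- .all_reversal_ops(n)
    nops <- ncol(ops)
    frontier <- matrix(seq_len(n), nrow = 1L)
    keys <- .row_keys(frontier)
    dist <- stats::setNames(0L, keys)
    level <- 0L
    while (nrow(frontier) > 0L) {
        level <- level + 1L
        cand <- vector("list", nops)
        for (j in seq_len(nops)) {
            a <- ops[1L, j]; b <- ops[2L, j]
            M <- frontier
            M[, a:b] <- -M[, b:a, drop = FALSE]
            cand[[j]] <- M
        }
        Mall <- do.call(rbind, cand)
        kall <- .row_keys(Mall)
        dup <- duplicated(kall)
        Mall <- Mall[!dup, , drop = FALSE]
        kall <- kall[!dup]
        new <- !(kall %in% names(dist))
        if (!any(new)) break
        frontier <- Mall[new, , drop = FALSE]
        knew <- kall[new]
        dist <- c(dist, stats::setNames(rep.int(level, length(knew)), knew))
    }
    dist
}

#' Brute-force BFS reversal distance between two genomes
#'
#' Frontier-by-frontier breadth-first search from `q` under all
#' inclusive-segment reversals until `p` is reached. Exact and symmetric;
#' refuses `n > 7`.
#'
#' @param p,q [SignedPermutation-class] objects with equal `n <= 7`.
#' @return Integer graph distance.
#' @export
bfsOracleDistance <- function(p, q) {
    stopifnot(is(p, "SignedPermutation"), is(q, "SignedPermutation"))
    n <- length(p@genes)
    if (length(q@genes) != n)
        stop("p and q must have the same number of genes")
    if (n > 7L)
        stop("BFS oracle is limited to n <= 7 (state space 2^n * n!)")
    target <- .perm_key(p@genes)
    frontier <- matrix(q@genes, nrow = 1L)
    seen <- .row_keys(frontier)
    if (seen == target) return(0L)
    ops <- .all_reversal_ops(n)
    nops <- ncol(ops)
    level <- 0L
    repeat {
        level <- level + 1L
        cand <- vector("list", nops)
        for (j in seq_len(nops)) {
            a <- ops[1L, j]; b <- ops[2L, j]
            M <- frontier
            M[, a:b] <- -M[, b:a, drop = FALSE]
            cand[[j]] <- M
        }
        Mall <- do.call(rbind, cand)
        kall <- .row_keys(Mall)
        dup <- duplicated(kall)
        Mall <- Mall[!dup, , drop = FALSE]
        kall <- kall[!dup]
        if (target %in% kall) return(level)
        new <- !(kall %in% seen)
        if (!any(new)) stop("state space exhausted without reaching target")
        frontier <- Mall[new, , drop = FALSE]
        seen <- c(seen, kall[new])
    }
}
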