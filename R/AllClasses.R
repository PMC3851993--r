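#' @import methods
NULL

## ---------------------------------------------------------------------------
## SignedPermutation
## ---------------------------------------------------------------------------

#' SignedPermutation: a unichromosomal gene order
#'
#' A signed permutation of length `n` models a single linear chromosome of
#' `n` genes: the absolute values give the gene order, the signs give each
#' gene's reading direction. The set of all such orderings is the signed
#' symmetric group of order `n`, which has `2^n * n!` elements.
#'
#' @slot genes Integer vector; the signed gene labels, one per chromosome
#'   slot. Absolute values must be exactly `1..n`, each once.
#'
#' @seealso [SignedPermutation()], [identityPermutation()],
#'   [applyReversal()], [relabel()]
#' @export
setClass("SignedPermutation", slots = c(genes = "integer"))

setValidity("SignedPermutation", function(object) {
    g <- object@genes
    n <- length(g)
    if (n < 1L)
        return("a signed permutation needs at least one gene")
    if (anyNA(g) || any(g == 0L))
        return("gene labels must be nonzero integers")
    if (!identical(sort(abs(g)), seq_len(n)))
        return(sprintf(
            "absolute gene labels must be exactly 1..%d, each once", n))
    TRUE
})

#' Construct a signed permutation
#'
#' @param genes Integer vector of signed gene labels whose absolute values
#'   are a permutation of `1..n`.
#' @return A [SignedPermutation-class] object.
#' @examples
#' SignedPermutation(c(1L, -3L, 2L))
#' @export
SignedPermutation <- function(genes) {
    new("SignedPermutation", genes = as.integer(genes))
}

## ---------------------------------------------------------------------------
## ReversalOp
## ---------------------------------------------------------------------------

#' ReversalOp: one reversal (inversion) operation
#'
#' A reversal reverses the order of a contiguous segment of the chromosome
#' and flips every sign inside it. The segment is addressed either by
#' 1-based inclusive positions (`mode = "positions"`, `a <= b`, singletons
#' allowed: a one-gene sign flip) or by two unsigned gene labels
#' (`mode = "elements"`), resolved to their current positions when applied.
#'
#' @slot a,b Integer segment bounds (positions) or gene labels (elements).
#' @slot mode Either `"positions"` or `"elements"`.
#' @export
setClass("ReversalOp",
    slots = c(a = "integer", b = "integer", mode = "character"))

setValidity("ReversalOp", function(object) {
    if (!object@mode %in% c("positions", "elements"))
        return("mode must be 'positions' or 'elements'")
    if (length(object@a) != 1L || length(object@b) != 1L)
        return("a and b must be single integers")
    if (object@a < 1L || object@b < 1L)
        return("a and b must be >= 1")
    if (object@mode == "positions" && object@a > object@b)
        return("positions mode requires a <= b")
    TRUE
})

#' Construct a reversal operation
#'
#' @param a,b Segment bounds: 1-based inclusive positions, or unsigned gene
#'   labels when `mode = "elements"`.
#' @param mode `"positions"` (default) or `"elements"`.
#' @return A [ReversalOp-class] object.
#' @examples
#' ReversalOp(2, 4)                      # reverse positions 2..4
#' ReversalOp(2, 4, mode = "elements")   # reverse the segment between genes 2 and 4
#' @export
ReversalOp <- function(a, b, mode = c("positions", "elements")) {
    mode <- match.arg(mode)
    new("ReversalOp", a = as.integer(a), b = as.integer(b), mode = mode)
}

## ---------------------------------------------------------------------------
## BreakpointGraph
## ---------------------------------------------------------------------------

#' BreakpointGraph: the bicoloured graph of two gene orders
#'
#' Vertices are gene extremities (in the standard unsigned doubling, gene
#' `+i` becomes the ordered point pair `(2i-1, 2i)` and `-i` becomes
#' `(2i, 2i-1)`, framed by points `0` and `2n+1`). Black edges join
#' extremities adjacent in the first genome, grey edges those adjacent in
#' the second (by construction the identity; general pairs are reduced via
#' [relabel()]). Every vertex has exactly one black and one grey edge, so
#' the graph decomposes into alternating cycles; the per-edge orientation
#' labels come from a counter-clockwise traversal started at each cycle's
#' left-most vertex along its black edge.
#'
#' @slot n Number of genes.
#' @slot points Integer vector of length `2n+2`: the doubled-point layout of
#'   the first genome on the extended line (left to right).
#' @slot blackEdges,greyEdges Two-column integer matrices of point pairs,
#'   `n+1` rows each.
#' @slot blackCycle,greyCycle Integer cycle index per black/grey edge.
#' @slot blackXi,greyXi Orientation labels (+1/-1) per black/grey edge.
#' @slot cycleLengths Integer vector: black-edge count of each cycle.
#' @seealso [buildBreakpointGraph()], [countCycles()], [classifyCycles()],
#'   [componentsHurdles()]
#' @export
setClass("BreakpointGraph",
    slots = c(n = "integer", points = "integer",
              blackEdges = "matrix", greyEdges = "matrix",
              blackCycle = "integer", greyCycle = "integer",
              blackXi = "integer", greyXi = "integer",
              cycleLengths = "integer"))

setValidity("BreakpointGraph", function(object) {
    n <- object@n
    m <- n + 1L
    if (nrow(object@blackEdges) != m || nrow(object@greyEdges) != m)
        return("a breakpoint graph must have n+1 black and n+1 grey edges")
    deg <- tabulate(c(object@blackEdges) + 1L, nbins = 2L * n + 2L)
    if (any(deg != 1L))
        return("every extremity must have exactly one black edge")
    degg <- tabulate(c(object@greyEdges) + 1L, nbins = 2L * n + 2L)
    if (any(degg != 1L))
        return("every extremity must have exactly one grey edge")
    if (sum(object@cycleLengths) != m)
        return("cycle black-edge counts must sum to n+1")
    if (!all(abs(object@blackXi) == 1L) || !all(abs(object@greyXi) == 1L))
        return("orientation labels must be +1 or -1")
    TRUE
})

## ---------------------------------------------------------------------------
## DistanceBreakdown
## ---------------------------------------------------------------------------

#' DistanceBreakdown: cycle/hurdle statistics and the two distances
#'
#' For a genome pair, records the number of alternating cycles `c` of the
#' breakpoint graph, the hurdle count `h` and fortress indicator `f`, and
#' the derived distances: DCJ distance `n + 1 - c` and reversal distance
#' `n + 1 - c + h + f` (the Hannenhalli-Pevzner formula).
#'
#' @slot n Number of genes.
#' @slot cycles,hurdles,fortress,dcj,reversal Integer statistics.
#' @seealso [distanceBreakdown()], [dcjDistance()], [reversalDistance()]
#' @export
setClass("DistanceBreakdown",
    slots = c(n = "integer", cycles = "integer", hurdles = "integer",
              fortress = "integer", dcj = "integer", reversal = "integer"))

setValidity("DistanceBreakdown", function(object) {
    if (object@dcj != object@n + 1L - object@cycles)
        return("dcj must equal n + 1 - cycles")
    if (object@reversal !=
        object@dcj + object@hurdles + object@fortress)
        return("reversal must equal dcj + hurdles + fortress")
    if (object@fortress < 0L || object@fortress > 1L)
        return("fortress must be 0 or 1")
    if (object@dcj < 0L || object@dcj > object@n + 1L)
        return("dcj out of range")
    TRUE
})

## ---------------------------------------------------------------------------
## WalkTrajectory and GenomeSet
## ---------------------------------------------------------------------------

#' WalkTrajectory: one reversal random walk
#'
#' A realisation of the reversal random walk: starting from the identity,
#' repeatedly pick a uniformly random reversal and apply it. The applied
#' operations are recorded as resolved 1-based position pairs so that
#' replaying them from the identity reproduces the endpoint exactly.
#'
#' @slot n Number of genes.
#' @slot ops Two-row integer matrix; column `s` holds the inclusive position
#'   bounds of the reversal applied at step `s`.
#' @slot sampling `"element_pairs"` (uniform unordered pair of distinct gene
#'   labels, `choose(n,2)` choices) or `"positions_with_singletons"`
#'   (uniform pair of the `n+1` black-edge gaps, `choose(n+1,2)` choices,
#'   includes one-gene sign flips).
#' @slot schedule `"fixed_steps"` or `"poisson_time"`.
#' @slot time Poisson mean (rate-1 clock) when scheduled by time, else `NA`.
#' @slot seed Integer seed used for this walk (`NA` if unseeded).
#' @slot endpoint The final [SignedPermutation-class].
#' @seealso [runWalk()], [distanceProfile()], [replayTrajectory()]
#' @export
setClass("WalkTrajectory",
    slots = c(n = "integer", ops = "matrix", sampling = "character",
              schedule = "character", time = "numeric", seed = "integer",
              endpoint = "SignedPermutation"))

#' GenomeSet: endpoints of k independent reversal walks
#'
#' Holds `k` independent walk trajectories started at the identity, each
#' driven by a child seed derived deterministically from the master seed
#' (the child seeds are drawn with `sample.int(2^31 - 2, k)` from a stream
#' seeded by the master seed).
#'
#' @slot n Number of genes.
#' @slot k Number of walks.
#' @slot walks List of [WalkTrajectory-class] objects.
#' @slot seed Master seed (`NA` if unseeded).
#' @seealso [runEnsemble()], [endpoints()]
#' @export
setClass("GenomeSet",
    slots = c(n = "integer", k = "integer", walks = "list",
              seed = "integer"))

setValidity("GenomeSet", function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (length(object@walks) != object@k)
        return("walks list length must equal k")
    TRUE
})

## ---------------------------------------------------------------------------
## MedianResult
## ---------------------------------------------------------------------------

#' MedianResult: the outcome of a median-value computation
#'
#' The median value of a genome set `A` is the minimum over all signed
#' permutations `x` of the total distance from `x` to the members of `A`.
#' A result is *closed* when the reported value is proved exact: either the
#' triangle-inequality lower bound met the best evaluated upper bound (a
#' certificate, no search needed) or the search space was exhausted. An
#' unclosed result carries a `[lower, upper]` interval and `NA` value.
#'
#' @slot value Exact median value, or `NA_real_` when not closed.
#' @slot lower,upper Certified bounds on the median value.
#' @slot witness A [SignedPermutation-class] attaining `upper` (the median
#'   solution itself when closed).
#' @slot method `"certificate"`, `"exhaustive"`, or `"branch_bound"`.
#' @slot nodes Number of candidate genomes evaluated.
#' @slot closed Logical: is `value` proved exact?
#' @seealso [medianExact()], [perimeterLowerBound()], [inputUpperBound()]
#' @export
setClass("MedianResult",
    slots = c(value = "numeric", lower = "numeric", upper = "numeric",
              witness = "SignedPermutation", method = "character",
              nodes = "numeric", closed = "logical"))

setValidity("MedianResult", function(object) {
    if (object@lower > object@upper)
        return("lower bound exceeds upper bound")
    if (object@closed && !is.na(object@value) &&
        (object@value < object@lower || object@value > object@upper))
        return("value must lie within [lower, upper]")
    TRUE
})

## ---------------------------------------------------------------------------
## PhaseSummary
## ---------------------------------------------------------------------------

#' PhaseSummary: the critical constant of the median phase change
#'
#' The critical constant `c*` is the root of `f(x/2) = 1/3`, where `f` is
#' the Erdos-Renyi tree-component series; beyond `c*` the total distance to
#' the identity provably exceeds an upper bound on the median value, so the
#' ancestral identity stops being a median solution.
#'
#' @slot cStar The root.
#' @slot residual `|f(cStar/2) - 1/3|`.
#' @slot bracket Bisection bracket used.
#' @slot iterations Number of bisection steps.
#' @seealso [solveCStar()], [fValue()], [alphaC()]
#' @export
setClass("PhaseSummary",
    slots = c(cStar = "numeric", residual = "numeric",
              bracket = "numeric", iterations = "integer"))
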