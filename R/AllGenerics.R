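#' Number of genes
#'
#' @param x A [SignedPermutation-class], [BreakpointGraph-class],
#'   [DistanceBreakdown-class], [WalkTrajectory-class] or
#'   [GenomeSet-class] object.
#' @return Integer `n`.
#' @export
setGeneric("numGenes", function(x) standardGeneric("numGenes"))

#' Signed gene order
#'
#' @param x A [SignedPermutation-class].
#' @return Integer vector of signed gene labels.
#' @export
setGeneric("geneOrder", function(x) standardGeneric("geneOrder"))

#' Apply a reversal to a signed permutation
#'
#' Reverses the inclusive segment addressed by `op` and flips every sign in
#' it. In `"elements"` mode the two gene labels are first resolved to their
#' current positions (in either order).
#'
#' @param x A [SignedPermutation-class].
#' @param op A [ReversalOp-class].
#' @return A new [SignedPermutation-class].
#' @examples
#' applyReversal(SignedPermutation(1:3), ReversalOp(1, 3))  # (-3,-2,-1)
#' @export
setGeneric("applyReversal", function(x, op) standardGeneric("applyReversal"))

#' Reduce a genome pair to a genome-versus-identity problem
#'
#' Returns `q^{-1} o p` under signed-permutation composition. All distances
#' here are left-invariant Cayley-graph metrics, so
#' `d(p, q) == d(relabel(p, q), id)`; every pairwise computation is reduced
#' to a comparison against the identity this way.
#'
#' @param p,q [SignedPermutation-class] objects with the same `n`.
#' @return A [SignedPermutation-class]; `relabel(p, p)` is the identity.
#' @export
setGeneric("relabel", function(p, q) standardGeneric("relabel"))

#' Number of alternating cycles
#'
#' @param x A [BreakpointGraph-class].
#' @return Integer cycle count; equals `n + 1` exactly for the identity.
#' @export
setGeneric("countCycles", function(x) standardGeneric("countCycles"))

#' Edge orientation labels
#'
#' Orientation of every edge under the counter-clockwise traversal
#' convention: each cycle is walked starting from its left-most vertex along
#' that vertex's black edge; a black edge is `+1` when walked left-to-right,
#' and a grey edge is `+1` when walked from its lower-numbered (gene-`i`)
#' extremity towards the gene-`(i+1)` extremity.
#'
#' @param x A [BreakpointGraph-class].
#' @return List with integer vectors `black` and `grey` (+1/-1 per edge).
#' @export
setGeneric("edgeOrientations",
    function(x) standardGeneric("edgeOrientations"))

#' Classify cycles as oriented or unoriented
#'
#' A cycle is oriented iff its black edges carry both orientation labels
#' (equivalently, some reversal acting on two of its black edges splits it).
#' Length-1 cycles are always unoriented.
#'
#' @param x A [BreakpointGraph-class].
#' @return A data.frame with columns `cycle`, `length` (black-edge count)
#'   and `oriented`.
#' @export
setGeneric("classifyCycles", function(x) standardGeneric("classifyCycles"))

#' Components, hurdles and the fortress indicator
#'
#' Cycles are grouped into components by the interleaving (crossing) of
#' their grey edges on the extended line. A component is unoriented iff it
#' contains no oriented cycle and spans more than one black edge. Hurdles
#' are the unoriented components that do not separate other unoriented
#' components (the minimal ones, plus the greatest one when it contains all
#' others); a super-hurdle is a hurdle whose deletion turns another
#' unoriented component into a hurdle; a fortress is an odd number of
#' hurdles, all of them super-hurdles.
#'
#' @param x A [BreakpointGraph-class].
#' @return List with `components` (data.frame: `component`, `cycles`,
#'   `spanStart`, `spanEnd`, `length`, `oriented`, `unoriented`, `hurdle`,
#'   `superHurdle`), `h` (hurdle count) and `fortress` (0/1).
#' @export
setGeneric("componentsHurdles",
    function(x) standardGeneric("componentsHurdles"))

#' DCJ distance
#'
#' `n + 1 - cycles` for a unichromosomal genome pair; also the
#' "approximate reversal distance" (the reversal distance with hurdles and
#' fortresses ignored).
#'
#' @param x A [SignedPermutation-class] or a [DistanceBreakdown-class].
#' @param y Optional second [SignedPermutation-class]; defaults to the
#'   identity.
#' @return Integer distance.
#' @export
setGeneric("dcjDistance", function(x, y) standardGeneric("dcjDistance"))

#' Reversal distance (Hannenhalli-Pevzner)
#'
#' `n + 1 - cycles + hurdles + fortress`.
#'
#' @inheritParams dcjDistance
#' @return Integer distance.
#' @export
setGeneric("reversalDistance",
    function(x, y) standardGeneric("reversalDistance"))

#' Walk endpoints as a genome collection
#'
#' @param x A [GenomeSet-class].
#' @return Named list of [SignedPermutation-class] endpoints
#'   (`walk1`, `walk2`, ...).
#' @export
setGeneric("endpoints", function(x) standardGeneric("endpoints"))
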