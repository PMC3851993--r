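## Signed permutations: constructors, reversal action, composition, sampling.

#' @describeIn numGenes length of a signed permutation
#' @export
setMethod("numGenes", "SignedPermutation", function(x) length(x@genes))

#' @describeIn geneOrder signed labels of a permutation
#' @export
setMethod("geneOrder", "SignedPermutation", function(x) x@genes)

setMethod("show", "SignedPermutation", function(object) {
    g <- object@genes
    cat(sprintf("SignedPermutation of %d genes\n", length(g)))
    cat(" ", paste(sprintf("%+d", g), collapse = " "), "\n")
})

#' The identity gene order
#'
#' @param n Positive integer number of genes.
#' @return The [SignedPermutation-class] `(+1, +2, ..., +n)`.
#' @examples
#' identityPermutation(3)
#' @export
identityPermutation <- function(n) {
    n <- as.integer(n)
    if (length(n) != 1L || is.na(n) || n < 1L)
        stop("n must be a positive integer")
    new("SignedPermutation", genes = seq_len(n))
}

#' A uniform random signed permutation
#'
#' Draws uniformly from all `2^n * n!` signed permutations using the
#' current RNG state (seed with [set.seed()] for reproducibility, or pass
#' `seed`).
#'
#' @param n Positive integer number of genes.
#' @param seed Optional integer seed applied before drawing.
#' @return A [SignedPermutation-class].
#' @export
randomPermutation <- function(n, seed = NULL) {
    n <- as.integer(n)
    if (length(n) != 1L || is.na(n) || n < 1L)
        stop("n must be a positive integer")
    if (!is.null(seed)) set.seed(seed)
    g <- sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
    new("SignedPermutation", genes = g)
}

## fast internal reversal on a raw integer vector (1-based inclusive)
.reverse_segment <- function(genes, a, b) {
    genes[a:b] <- -rev(genes[a:b])
    genes
}

#' @describeIn applyReversal positions mode reverses slots `a..b`
#'   (singletons allowed); elements mode resolves the two labels to their
#'   current positions first.
#' @export
setMethod("applyReversal", c("SignedPermutation", "ReversalOp"),
    function(x, op) {
        g <- x@genes
        n <- length(g)
        if (op@mode == "positions") {
            a <- op@a; b <- op@b
            if (a < 1L || b > n || a > b)
                stop(sprintf("invalid reversal positions (%d, %d) for n = %d",
                             op@a, op@b, n))
        } else {
            if (op@a > n || op@b > n)
                stop(sprintf("unknown gene label(s) (%d, %d) for n = %d",
                             op@a, op@b, n))
            pos <- match(c(op@a, op@b), abs(g))
            a <- min(pos); b <- max(pos)
        }
        new("SignedPermutation", genes = .reverse_segment(g, a, b))
    })

## signed composition (q o p)(i) = q(p(i)), signs multiply
.compose <- function(q, p) {
    as.integer(sign(p)) * q[abs(p)]
}

## signed inverse: maps gene g back to its slot, with g's sign
.invert <- function(p) {
    inv <- integer(length(p))
    inv[abs(p)] <- as.integer(sign(p)) * seq_along(p)
    inv
}

#' @describeIn relabel method for two signed permutations
#' @export
setMethod("relabel", c("SignedPermutation", "SignedPermutation"),
    function(p, q) {
        if (length(p@genes) != length(q@genes))
            stop("relabel needs two permutations of the same length")
        new("SignedPermutation",
            genes = .compose(.invert(q@genes), p@genes))
    })

## internal: relabel on raw vectors
.relabel_vec <- function(p, q) .compose(.invert(q), p)

## relabel every row of a state matrix against q (vectorised)
.relabel_rows <- function(M, q) {
    qinv <- .invert(q)
    R <- matrix(qinv[abs(M)], nrow = nrow(M))
    R * sign(M)
}

.perm_key <- function(genes) paste(genes, collapse = " ")

.row_keys <- function(M) do.call(paste, as.data.frame(M))

#' Enumerate the whole signed symmetric group
#'
#' All `2^n * n!` signed permutations as the rows of an integer matrix.
#' Intended for exhaustive computations at small `n`.
#'
#' @param n Number of genes; capped at 7 (`2^7 * 7! = 645120` states).
#' @return Integer matrix with `n` columns, one state per row.
#' @export
enumerateSignedPermutations <- function(n) {
    n <- as.integer(n)
    if (n < 1L || n > 7L)
        stop("exhaustive enumeration is limited to 1 <= n <= 7")
    perms <- function(v) {
        if (length(v) == 1L) return(matrix(v, 1L))
        out <- vector("list", length(v))
        for (i in seq_along(v)) {
            rest <- perms(v[-i])
            out[[i]] <- cbind(v[i], rest, deparse.level = 0L)
        }
        do.call(rbind, out)
    }
    P <- perms(seq_len(n))
    S <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n),
                               KEEP.OUT.ATTRS = FALSE))
    dimnames(S) <- NULL
    nr <- nrow(P); ns <- nrow(S)
    P[rep(seq_len(nr), each = ns), , drop = FALSE] *
        S[rep(seq_len(ns), times = nr), , drop = FALSE]
}

## canonical order rank: -n < ... < -1 < +1 < ... < +n
.canonical_ranks <- function(M, n) {
    ifelse(M < 0L, M + n + 1L, M + n)
}
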