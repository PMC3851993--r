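## The Erdos-Renyi tree-component limit function
##
##     f(c) = (1/c) * sum_{k>=1} k^{k-2}/k! * (c e^{-c})^k ,
##
## the limiting fraction (per vertex) of tree components of G(n, c/n).
## It equals 1 - c/2 for c <= 1 and is strictly decreasing; it governs the
## normalized distance of the reversal walk (distance/n -> 1 - f(c) after
## cn/2 steps) and, through f(x/2) = 1/3, the critical constant of the
## median phase change.

#' Tree-component series f(c)
#'
#' Evaluates the series directly, with each term computed in log space
#' (`(k-2) log k - lgamma(k+1) + k log(c e^{-c})`) to avoid overflow of
#' `k^{k-2}/k!`. Summation stops when a geometric tail estimate, based on
#' the observed term ratio, falls below the tolerance; if the cap on the
#' number of terms is reached first, the call fails rather than returning
#' a silent partial value.
#'
#' @param c Positive evaluation point.
#' @param tol Absolute tolerance on the sum (default `1e-10`).
#' @param maxTerms Cap on the number of terms (default `2e6`; the series
#'   decays only like `k^(-5/2)` near `c = 1`, so the cap is large).
#' @return Value in `(0, 1]`, with attribute `"terms"` (terms summed) and
#'   `"tail"` (the final tail estimate).
#' @examples
#' fSeries(0.5)   # 0.75: closed form 1 - c/2 below 1
#' fSeries(2)     # about 0.162
#' @export
fSeries <- function(c, tol = 1e-10, maxTerms = 2e6) {
    if (length(c) != 1L || is.na(c) || c <= 0)
        stop("c must be a single positive number")
    if (tol <= 0) stop("tol must be > 0")
    if (maxTerms < 1) stop("maxTerms must be >= 1")
    x <- log(c) - c                 # log(c e^{-c})
    chunk <- 50000L
    total <- 0
    k0 <- 1L
    tail_est <- Inf
    repeat {
        k <- k0:min(k0 + chunk - 1L, maxTerms)
        lt <- (k - 2) * log(k) - lgamma(k + 1) + k * x
        terms <- exp(lt)
        total <- total + sum(terms)
        last <- terms[length(terms)]
        prev <- if (length(terms) >= 2L) terms[length(terms) - 1L]
                else terms[1L]
        r <- if (prev > 0) last / prev else 0
        tail_est <- if (r < 1 && last > 0) last * r / (1 - r) else
                    if (last == 0) 0 else Inf
        if (tail_est < tol) break
        if (max(k) >= maxTerms)
            stop(sprintf(
                "f(c) series did not converge to %g within %d terms (tail estimate %g)",
                tol, as.integer(maxTerms), tail_est))
        k0 <- max(k) + 1L
    }
    val <- total / c
    val <- min(max(val, .Machine$double.xmin), 1)
    attr(val, "terms") <- max(k)
    attr(val, "tail") <- tail_est
    val
}

#' The limit function f with its closed form below 1
#'
#' Dispatches to the closed form `1 - c/2` for `c <= 1` (where `1 - f` is
#' exactly linear) and to [fSeries()] for `c > 1`; the two branches agree
#' at `c = 1` to within the series tolerance.
#'
#' @param c Positive evaluation point (vectorised).
#' @param tol,maxTerms Passed to [fSeries()].
#' @return Numeric vector of values in `(0, 1)`.
#' @export
fValue <- function(c, tol = 1e-10, maxTerms = 2e6) {
    if (any(is.na(c)) || any(c <= 0)) stop("c must be positive")
    vapply(c, function(ci) {
        if (ci <= 1) 1 - ci / 2
        else as.numeric(fSeries(ci, tol = tol, maxTerms = maxTerms))
    }, numeric(1L))
}

#' Solve for the critical constant c*
#'
#' Bisects `g(x) = f(x/2) - 1/3` on the bracket; `f` is strictly
#' decreasing, so the root is unique. Bisection (not a derivative method)
#' because `f` is cheap and monotone.
#'
#' @param bracket Two positive numbers straddling the root (default
#'   `c(0.5, 9)`).
#' @param xtol Absolute tolerance on the root (default `1e-6`).
#' @return A [PhaseSummary-class].
#' @examples
#' solveCStar()   # about 2.745, between 2 and 3
#' @export
solveCStar <- function(bracket = c(0.5, 9), xtol = 1e-6) {
    stopifnot(length(bracket) == 2L, all(bracket > 0))
    lo <- min(bracket); hi <- max(bracket)
    g <- function(x) fValue(x / 2) - 1 / 3
    glo <- g(lo); ghi <- g(hi)
    if (sign(glo) == sign(ghi))
        stop("bracket does not straddle the root of f(x/2) = 1/3")
    it <- 0L
    while (hi - lo > xtol) {
        it <- it + 1L
        mid <- (lo + hi) / 2
        gm <- g(mid)
        if (sign(gm) == sign(glo)) { lo <- mid; glo <- gm } else hi <- mid
    }
    root <- (lo + hi) / 2
    new("PhaseSummary", cStar = root, residual = abs(g(root)),
        bracket = as.numeric(bracket), iterations = it)
}

setMethod("show", "PhaseSummary", function(object) {
    cat(sprintf("Critical constant c* = %.6f\n", object@cStar))
    cat(sprintf("  root of f(x/2) = 1/3; residual %.2e; bracket [%g, %g]; %d bisection steps\n",
                object@residual, object@bracket[1L], object@bracket[2L],
                object@iterations))
})

#' Above-phase error constant alpha_c
#'
#' `alpha_c = k (1 - f(2c))`: the order-n error rate of the median value as
#' a divergence-time estimator after `cn` steps per walk; strictly positive
#' for `c > 1/2`.
#'
#' @param c Clock constant, `> 1/2`.
#' @param k Number of walks (`>= 1`).
#' @return Positive number.
#' @export
alphaC <- function(c, k) {
    if (any(c <= 1 / 2))
        stop("alpha_c is defined for c > 1/2")
    if (any(k < 1)) stop("k must be >= 1")
    k * (1 - fValue(2 * c))
}

#' Predicted normalized walk distance
#'
#' After `u` reversals on `n` genes the DCJ (and reversal) distance to the
#' identity concentrates at `(1 - f(2u/n)) n`; this returns the fraction
#' `1 - f(2u/n)`, which equals `u/n` in the linear regime `2u/n <= 1`.
#'
#' @param u Nonnegative step count.
#' @param n Positive gene count.
#' @return Value in `[0, 1)`.
#' @export
predictedFraction <- function(u, n) {
    stopifnot(u >= 0, n >= 1)
    if (u == 0) return(0)
    1 - fValue(2 * u / n)
}

#' Empirical tree-component fraction of an Erdos-Renyi graph
#'
#' Samples `G(n, c/n)` (each of the `choose(n, 2)` edges independently
#' present with probability `c/n`), counts connected components that are
#' trees (edge count = vertex count - 1; isolated vertices included) and
#' returns the count divided by `n` — the statistic whose limit is `f(c)`.
#' Sampling draws a binomial edge count and then that many distinct
#' uniform pairs, which is equivalent in distribution.
#'
#' @param n Number of vertices (`>= 10`).
#' @param c Positive constant with `c/n <= 1`.
#' @param seed Optional integer seed.
#' @return Tree-component fraction in `[0, 1]`.
#' @export
erTreeComponentFraction <- function(n, c, seed = NULL) {
    n <- as.integer(n)
    if (n < 10L) stop("n must be >= 10")
    if (c <= 0 || c / n > 1) stop("need 0 < c/n <= 1")
    if (!is.null(seed)) set.seed(seed)
    npairs <- n * (n - 1) / 2
    m <- stats::rbinom(1L, size = npairs, prob = c / n)
    if (m > 0L) {
        idx <- sample(npairs, m) - 1          # 0-based pair index
        ## pair index -> (i, j), i < j, rows in increasing i
        i <- floor(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
        ## guard against sqrt rounding at the row boundaries
        first <- function(i) i * n - i * (i + 1) / 2   # first index of row i
        i <- pmax(0, pmin(n - 2, i))
        i <- ifelse(first(i) > idx, i - 1, i)
        i <- ifelse(first(i + 1) <= idx, i + 1, i)
        j <- idx - first(i) + i + 1
        ek <- cbind(as.integer(i) + 1L, as.integer(j) + 1L)
    } else {
        ek <- matrix(integer(0L), ncol = 2L)
    }
    ## union-find with per-component edge tallies
    parent <- seq_len(n)
    find <- function(v) {
        while (parent[v] != v) {
            parent[v] <<- parent[parent[v]]
            v <- parent[v]
        }
        v
    }
    edges_in <- integer(n)
    for (e in seq_len(nrow(ek))) {
        ra <- find(ek[e, 1L])
        rb <- find(ek[e, 2L])
        if (ra == rb) {
            edges_in[ra] <- edges_in[ra] + 1L
        } else {
            parent[rb] <- ra
            edges_in[ra] <- edges_in[ra] + edges_in[rb] + 1L
        }
    }
    roots <- vapply(seq_len(n), find, integer(1L))
    sizes <- tabulate(roots, nbins = n)
    comp <- which(sizes > 0L)
    ntrees <- sum(edges_in[comp] == sizes[comp] - 1L)
    ntrees / n
}
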