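# Independent oracles used across the suite. Each restates the relevant
# definition from scratch so that it shares no code path with the
# implementation it checks.

# random signed permutation as a raw integer vector
rand_perm <- function(n) {
  sample.int(n) * sample(c(-1L, 1L), n, replace = TRUE)
}

# Union-find recount of breakpoint-graph cycles: lay out the doubled
# points, union across every black and grey adjacency, count components.
uf_cycle_count <- function(genes) {
  n <- length(genes)
  pts <- integer(0)
  for (g in genes) {
    pts <- c(pts, if (g > 0L) c(2L * g - 1L, 2L * g)
                  else c(-2L * g, -2L * g - 1L))
  }
  pts <- c(0L, pts, 2L * n + 1L)
  parent <- seq_len(2L * n + 2L)          # index = point + 1
  find <- function(v) {
    while (parent[v] != v) {
      parent[v] <<- parent[parent[v]]
      v <- parent[v]
    }
    v
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  for (j in seq_len(n + 1L))
    unite(pts[2L * j - 1L] + 1L, pts[2L * j] + 1L)   # black adjacencies
  for (i in 0:n)
    unite(2L * i + 1L, 2L * i + 2L)                  # grey adjacencies
  length(unique(vapply(seq_len(2L * n + 2L), find, integer(1L))))
}

# High-precision direct summation of the tree-component series with a
# fixed term count and ascending-order accumulation (no adaptive
# stopping; independent of fSeries' chunked tail logic).
f_series_oracle <- function(c, kmax = 2e5) {
  k <- seq_len(kmax)
  lt <- (k - 2) * log(k) - lgamma(k + 1) + k * (log(c) - c)
  sum(sort(exp(lt))) / c
}

# Greedy sorting certificate: repeatedly apply any reversal that lowers
# the Hannenhalli-Pevzner distance by exactly one. Returns the number of
# reversals used to reach the identity, or -1 when stuck; equality with
# the claimed distance exhibits an actual sorting scenario of that
# length.
greedy_sort_len <- function(g) {
  n <- length(g)
  d <- reversalDistance(SignedPermutation(g))
  steps <- 0L
  while (d > 0L) {
    advanced <- FALSE
    for (a in seq_len(n)) {
      for (b in a:n) {
        g2 <- g
        g2[a:b] <- -rev(g2[a:b])
        if (reversalDistance(SignedPermutation(g2)) == d - 1L) {
          g <- g2; d <- d - 1L; steps <- steps + 1L; advanced <- TRUE
          break
        }
      }
      if (advanced) break
    }
    if (!advanced) return(-1L)
  }
  steps
}

# A fortress instance constructed from three disjoint copies of an
# 8-gene block whose breakpoint graph is a nested pair of unoriented
# components (synthetic: built by nesting, not taken from data).
fortress_permutation <- function() {
  blk <- c(1L, 3L, 5L, 4L, 6L, 2L, 7L, 8L)
  c(blk, blk + 8L, blk + 16L)
}
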