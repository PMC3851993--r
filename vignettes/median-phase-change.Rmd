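---
title: "Reversal walks, rearrangement distances and the median-value phase change"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reversal walks, rearrangement distances and the median-value phase change}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medianwalk)
```

## The model

A unichromosomal genome with `n` genes is a *signed permutation*: the
absolute values give the gene order, the sign gives each gene's reading
direction. Genomes evolve by *reversals* (inversions): a contiguous
segment is reversed and every sign in it flipped. Evolution is modelled
as a random walk: starting from the ancestor `id = (+1, ..., +n)`, a
uniformly random reversal is applied at each event of a rate-1 Poisson
clock, so after time `t` about `t` reversals have occurred. For
reproducible experiments the package defaults to a fixed step count `u`;
the Poisson schedule (`runWalk(n, time = t)`) exists because the
continuous-time model is the natural one, and at the scales of interest
`u` and `t` are interchangeable.

Two metrics are supported, both read off the *breakpoint graph* of a
genome pair. Gene extremities form the vertices; black edges encode the
adjacencies of one genome, grey edges those of the other; the graph
decomposes into alternating cycles. With `c` cycles, `h` hurdles and
fortress indicator `f`:

* DCJ distance: `d_dcj = n + 1 - c` (also the "approximate reversal
  distance": reversal distance with hurdles and fortresses ignored);
* reversal distance (Hannenhalli–Pevzner): `d_r = n + 1 - c + h + f`.

Given `k >= 3` genomes `A = {X1, ..., Xk}`, the *median value* is

```
m(A) = min over all genomes x of  g_A(x),   g_A(x) = sum_i d(x, Xi),
```

and the question the package is built to study is: when the `Xi` are
endpoints of `k` independent reversal walks of `u` steps, does `m(A)`
recover `k * u`, the total divergence time? The answer is a phase
change: *yes* while `u < n/4` (and the ancestor `id` itself is a median
solution), *no* once `u` is large enough — quantified below by the
critical constant `c*`.

## The limit function f(c)

The walk's speed is governed by the function

```
f(c) = (1/c) * sum_{k >= 1} k^(k-2)/k! * (c e^{-c})^k ,
```

the limiting fraction (per vertex) of *tree components* of an
Erdős–Rényi random graph `G(n, c/n)`. After `u = c n / 2` reversals the
normalized distance `d(id, X_u)/n` concentrates at `1 - f(c)`. Below
`c = 1` this is exactly linear (`f(c) = 1 - c/2`): the walk travels on a
geodesic and distance equals the number of steps. Above `c = 1` it is
sublinear: the walk wastes steps.

Numerical notes:

* Terms are computed in log space (`lgamma`-based), since `k^(k-2)/k!`
  overflows past `k` around 170.
* Near `c = 1` the terms decay only like `k^(-5/2)`, so truncating when
  a term is small underestimates the tail badly. `fSeries()` instead
  stops when a geometric tail bound — the last term times
  `r/(1 - r)` with `r` the observed term ratio — drops below the
  tolerance (`1e-10` by default), and fails loudly if the 2-million-term
  cap is hit first. At `c = 1` this needs about 1.4 million terms and
  still runs in well under a second.
* `fValue()` dispatches to the closed form `1 - c/2` for `c <= 1`; the
  two branches agree at `c = 1` to below `1e-6`.
* The normalization of the tree-component count (per vertex, i.e.
  divided by `n`) is fixed by two checks in the test suite: `f -> 1` as
  `c -> 0` (isolated vertices are trivial trees) and agreement with the
  closed form. `erTreeComponentFraction()` simulates `G(n, c/n)`
  directly (binomial edge count, then distinct uniform pairs;
  union-find with per-component edge tallies) and reproduces `f` to
  within 0.01 at `n = 20000`.

```{r fcurve}
fValue(c(0.25, 0.5, 1, 2))
```

## Distances and their validation

All metrics here are left-invariant Cayley-graph metrics, so every pair
`(p, q)` is reduced to `(relabel(p, q), id)` with
`relabel(p, q) = q^{-1} ∘ p`. The breakpoint graph is built in the
standard unsigned doubling (gene `+i` becomes points `(2i-1, 2i)`,
`-i` becomes `(2i, 2i-1)`, frame points `0` and `2n+1`); this makes the
orientation convention concrete: each cycle is traversed starting from
its left-most vertex along its black edge, a black edge is positively
oriented when walked left to right, and a cycle is *oriented* iff its
black edges carry both labels. A reversal acting on two black edges
merges their cycles if they differ, splits the cycle if the two edges
are crossing (opposite labels), and otherwise leaves the count
unchanged — a property the test suite verifies by direct simulation.

Hurdles and fortresses are defined in several equivalent ways in the
literature; the package adopts the standard characterization: components are groups
of cycles connected by *interleaving* (strictly crossing) grey edges; a
component is unoriented iff it contains no oriented cycle and more than
one black edge; an unoriented component is a *hurdle* iff it does not
have unoriented components both strictly inside and outside its span; a
*super-hurdle* protects another unoriented component (deleting it turns
a non-hurdle into a hurdle); a *fortress* is an odd number of hurdles,
all super. Note interleaving, not mere span overlap, is the right
grouping relation — span overlap would merge nested components that do
not cross.

Correctness is anchored in two independent ways:

1. a brute-force BFS oracle on the reversal Cayley graph
   (`bfsDistanceTable()`, `bfsOracleDistance()`): the assembled formula
   matches exact graph distances on *all* of the `n = 2` and `n = 3`
   groups and on hundreds of random genomes at `n = 5` and `n = 6`;
2. since no fortress exists at BFS-tractable sizes, the fortress branch
   is validated on a constructed instance (three disjoint copies of an
   8-gene block whose graph is a nested pair of unoriented components)
   together with a *sorting certificate*: greedily following the
   formula downhill reaches the identity in exactly the formula's
   number of reversals, exhibiting an actual scenario of that length.
   This certificate is also asserted for random permutations at
   `n = 10`–`12`, which exercises hurdle configurations beyond BFS
   reach. The residual risk — a systematic error that both the formula
   and the greedy certificate miss — would require the formula to
   *under*-count, which the BFS equivalence rules out at small `n`.

```{r fortress}
fort <- SignedPermutation(c(1L,3L,5L,4L,6L,2L,7L,8L,
                            9L,11L,13L,12L,14L,10L,15L,16L,
                            17L,19L,21L,20L,22L,18L,23L,24L))
distanceBreakdown(fort)
```

## Walk sampling choices

The walk draws an unordered pair of distinct *gene labels* (uniform over
`choose(n, 2)` pairs) and reverses the segment between their current
positions — the literal reading of "choose two elements". A second mode,
`positions_with_singletons`, draws a pair of the `n + 1` black-edge gaps
(`choose(n+1, 2)` choices, one-gene sign flips included), matching how
reversals act on the breakpoint graph. The limit law does not
distinguish them, and the scaling tests pass under both. Singleton sign
flips are legal as explicit operations in positions mode but excluded
from the default sampling, which also means `i = j` draws never occur;
the BFS oracle, by contrast, deliberately includes singleton reversals
in its move set since the reversal distance is defined over all
reversals. The Poisson clock is read as a single global rate-1 clock
(not rate 1 per pair): the theory's scales — time `cn/2` producing about
`cn/2` reversals — force that reading.

Ensembles derive per-walk child seeds from the master seed by a fixed
documented rule (`sample.int(2^31 - 2, k)` on a stream seeded with the
master), so every experiment row is reproducible in isolation.

## Median machinery

Three quantities bracket the median value:

* the *perimeter bound* `ceil(sum_{i<j} d(Xi, Xj) / (k - 1))`, from the
  triangle inequality summed over unordered pairs (the unordered-pair
  form is used; the exhaustive solver confirms its validity on random
  instances);
* the *input bound* `min_x g_A(x)` over `x` in `A ∪ {id}`;
* exact search: exhaustive enumeration of all `2^n n!` genomes
  (`n <= 6`), or best-first branch-and-bound over the reversal graph
  seeded at the bound witnesses.

When the two bounds meet, the value is *certified* without any search —
this is what makes below-phase experiments at `n = 100` feasible, and it
mirrors exactly how the theory pins the median between the perimeter
bound and `g_A(id)`. The branch-and-bound search has no sound per-node
lower bound tighter than the global perimeter bound (one reversal can
lower `g` by up to `k`), so it *closes* — reports a proved-exact
value — only when the incumbent meets the perimeter bound or the whole
space has been enumerated; otherwise it returns an explicitly flagged
open interval `[lower, upper]`, never a silent approximation. Witness
ties are broken by canonical order on signed sequences
(`-n < ... < -1 < +1 < ... < +n`, slot by slot) for determinism.

## The phase change, at desk scale

Below the phase (`u < n/4`), pairwise endpoint distances concentrate at
`2u` and each `d(id, Xi)` at `u`, so the perimeter bound
(`ceil(k * 2u / 2) = k u` for `k = 3`) meets `g_A(id) = k u`: the
certificate proves `m = k u` and `epsilon = g_A(id) - m = 0` — the
median value recovers `k` times the divergence time and the ancestor is
a median solution. `phaseExperiment()` reports the certificate success
rate, which decays as `u` crosses the phase.

Above the phase (clock `u = c n / 4` per walk), an input genome reaches
the other two in about `2 (1 - f(c)) n` while the identity needs
`3 (1 - f(c/2)) n`; once
`3 (1 - f(c/2)) > 2 (1 - f(c))` — guaranteed past the critical constant
`c*` solving `f(x/2) = 1/3` — the identity is provably not a median
solution and the error is of order `n` (rate `alpha_c = k (1 - f(2c))`
after `cn` steps). `abovePhaseExperiment()` certifies this with the
bounds alone: `epsilon >= g_A(id) - min_i g_A(Xi)`, no solver needed.

```{r cstar}
solveCStar()
```

The critical constant is computed by bisection of `f(x/2) - 1/3` on
`[0.5, 9]` to `1e-6` (the exact rational `1/3` is used in the
residual); monotonicity of `f` makes the root unique, and independent
brackets agree to `1e-6`. The root, about `2.738`, lies strictly
between 2 and 3.

Because exact medians are hopeless at large `n`, the experiments never
attempt to locate the empirical phase point beyond these
certificate/bound proxies — which is precisely the information the
theory itself uses. The constants multiplying `n` in the above-phase
error (beyond the `alpha_c` rate) have no closed form; the tables
report empirical `epsilon/n` instead.

## Experiment design and problem sizes

Two clocks are deliberately exposed, because the theory uses both: the
two-genome scaling and hurdle studies parameterise `c` by `u = c n / 2`;
the `k`-walk median studies by `u = c n / 4`; the above-phase error rate
by `u = c n`. Every table records `u` and `n` explicitly.

Default study conditions (chosen once, as the conditions under which
the phenomena are cleanly visible at a desk): scaling and hurdle runs
use `n = 2000` with 20 replicates per grid point; the below-phase
median study `n = 100, k = 3, u = 10` with 20 replicates; the
above-phase study `n = 500, k = 3, u = 1500` with 10 replicates; ball
volumes `n = 300, c = 0.8` with 2000 uniform draws; random-graph checks
`n = 20000` with 5 replicates. The diagnostic residual columns are
scaled by `a_n sqrt(n)` with `a_n = log n`; any diverging sequence is
admissible and the choice only rescales that column.

What the simulator does *not* emulate about real genomes: genes are
unique (no duplication or loss), chromosomes are single and linear, and
all reversals are equally likely regardless of length. Passing tests
therefore say nothing about, e.g., short-reversal-biased evolution or
multichromosomal rearrangement; they validate the mathematics of this
model, not the realism of the model itself.

## Degenerate inputs and edge conventions

`n = 1` is legal everywhere except element-pair walk sampling (which
needs two distinct labels); `u = 0` walks return the identity and all
experiments handle the `c = 0` grid point exactly (distance 0, residual
0). Ties in `inputUpperBound()` keep the first candidate in input order
(the identity is evaluated last). The perimeter bound uses integer
ceiling division, so certificates are exact integer statements, never
floating-point comparisons.

## Known limitations

* Reversal distances rely on the hurdle machinery being right at all
  `n`; beyond BFS reach this is supported by the sorting certificate
  and the constructed fortress, not by exhaustive proof.
* `medianExact()` is exact only for `n <= 6` (enumeration) or when a
  certificate closes; in between it returns intervals.
* Component detection is `O(n^2)` by design (desk scale,
  `n` up to a few thousand); no linear-time machinery.
* Multichromosomal and circular genomes, unsigned permutations, and
  operation sets other than reversals (transpositions, general DCJ
  walks) are out of scope, as is any tree search over phylogenies.
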