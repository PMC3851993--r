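Package: medianwalk
Title: Rearrangement Distances, Reversal Random Walks and the Median-Value
    Phase Change
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how well the genome-median value estimates
    divergence time under random rearrangement evolution. Implements signed
    permutations of gene orders with GRIMM-style input/output, breakpoint
    graphs with oriented-cycle classification and Hannenhalli-Pevzner
    hurdle/fortress detection, exact DCJ and reversal distances with a
    brute-force BFS oracle for small gene numbers, reversal random walks
    (fixed step count or rate-1 Poisson clock) and ensembles of independent
    walks, exact and certified median-value solvers with triangle-inequality
    lower bounds, the Erdos-Renyi tree-component limit function f(c) with its
    phase constants (including the critical constant solving f(x/2) = 1/3),
    and seeded experiment drivers that reproduce the distance-scaling, hurdle
    scarcity, median phase-change and ball-volume phenomena at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, igraph
Suggests: testthat (>= 3.0.0), jsonlite, optparse, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
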