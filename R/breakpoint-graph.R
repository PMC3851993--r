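## Breakpoint graph construction, cycle decomposition, orientation,
## components, hurdles and fortresses.
##
## Internal representation: the standard unsigned doubling. Gene +i becomes
## the ordered point pair (2i-1, 2i), gene -i becomes (2i, 2i-1); the line
## is framed by points 0 (left) and 2n+1 (right). Black edges join points
## adjacent across a gap of the first genome; grey edges are the identity
## adjacencies (2i, 2i+1), i = 0..n. Grey edge j (j = 1..n+1) connects
## points 2(j-1) and 2(j-1)+1.

## group-wise aggregation that preserves numeric group order 1..nlev
.by_group <- function(x, g, nlev, fun) {
    as.vector(tapply(x, factor(g, levels = seq_len(nlev)), fun))
}

## Build the graph for `genes` against the identity.
## Returns a plain list (hot path); wrap with buildBreakpointGraph() for S4.
.bp_build <- function(genes) {
    n <- length(genes)
    np <- 2L * n + 2L
    left <- ifelse(genes > 0L, 2L * genes - 1L, -2L * genes)
    right <- ifelse(genes > 0L, 2L * genes, -2L * genes - 1L)
    pts <- c(0L, as.integer(rbind(left, right)), 2L * n + 1L)
    pos <- integer(np)
    pos[pts + 1L] <- seq_len(np)          # 1-based linear position per point
    nb <- n + 1L
    odd <- seq(1L, np - 1L, by = 2L)
    bu <- pts[odd]                         # black edge j: (bu[j], bv[j])
    bv <- pts[odd + 1L]
    bpart <- integer(np)
    bpart[bu + 1L] <- bv
    bpart[bv + 1L] <- bu
    blackId <- integer(np)
    blackId[bu + 1L] <- seq_len(nb)
    blackId[bv + 1L] <- seq_len(nb)

    blackCycle <- integer(nb)
    blackXi <- integer(nb)
    greyCycle <- integer(nb)
    greyXi <- integer(nb)
    cycleLengths <- integer(0L)
    visited <- logical(nb)
    ncyc <- 0L
    be <- integer(nb); bd <- integer(nb)   # per-cycle scratch
    ge <- integer(nb); gd <- integer(nb)
    bs <- integer(nb)                      # black-step start points

    for (e0 in seq_len(nb)) {
        if (visited[e0]) next
        ncyc <- ncyc + 1L
        u0 <- bu[e0]
        cur <- u0
        len <- 0L
        minpos <- pos[u0 + 1L]
        minpt <- u0
        repeat {
            len <- len + 1L
            bs[len] <- cur
            eb <- blackId[cur + 1L]
            be[len] <- eb
            visited[eb] <- TRUE
            nxt <- bpart[cur + 1L]
            bd[len] <- if (pos[cur + 1L] < pos[nxt + 1L]) 1L else -1L
            if (pos[cur + 1L] < minpos) { minpos <- pos[cur + 1L]; minpt <- cur }
            if (pos[nxt + 1L] < minpos) { minpos <- pos[nxt + 1L]; minpt <- nxt }
            ## grey step from nxt: partner flips the last bit
            gto <- if (nxt %% 2L == 0L) nxt + 1L else nxt - 1L
            ge[len] <- nxt %/% 2L + 1L
            gd[len] <- if (nxt %% 2L == 0L) 1L else -1L
            cur <- gto
            if (cur == u0) break
        }
        idx <- seq_len(len)
        ## Convention: traverse from the cycle's left-most vertex along its
        ## black edge. Our walk left every bs[] point via black; if the
        ## left-most vertex is not one of them, the walk ran the other way
        ## round and every orientation label flips.
        flip <- !(minpt %in% bs[idx])
        sgn <- if (flip) -1L else 1L
        blackCycle[be[idx]] <- ncyc
        blackXi[be[idx]] <- sgn * bd[idx]
        greyCycle[ge[idx]] <- ncyc
        greyXi[ge[idx]] <- sgn * gd[idx]
        cycleLengths <- c(cycleLengths, len)
    }
    list(n = n, pts = pts, pos = pos,
         blackU = bu, blackV = bv,
         blackCycle = blackCycle, blackXi = blackXi,
         greyCycle = greyCycle, greyXi = greyXi,
         cycleLengths = cycleLengths, ncyc = ncyc)
}

## Hurdle and fortress counts from a .bp_build() list.
## Returns c(h, fortress). Cheap shortcut: hurdles need at least one
## unoriented cycle of length > 1 (trivial cycles are isolated components
## and oriented cycles orient their component).
.hp_counts <- function(bp) {
    n <- bp$n
    lens <- bp$cycleLengths
    ncyc <- bp$ncyc
    posOr <- .by_group(bp$blackXi > 0L, bp$blackCycle, ncyc, any)
    negOr <- .by_group(bp$blackXi < 0L, bp$blackCycle, ncyc, any)
    orientedCycle <- posOr & negOr
    if (!any(lens > 1L & !orientedCycle))
        return(c(0L, 0L))

    ## component membership: union cycles whose grey edges cross
    m <- n + 1L
    gidx <- seq_len(m)
    p1 <- bp$pos[2L * (gidx - 1L) + 1L]        # pos of point 2(j-1)
    p2 <- bp$pos[2L * (gidx - 1L) + 2L]        # pos of point 2(j-1)+1
    a <- pmin(p1, p2)
    b <- pmax(p1, p2)
    ## drop length-1 grey edges: they cannot cross anything
    keep <- which(b - a > 1L)
    memb <- seq_len(ncyc)
    if (length(keep) > 1L) {
        ak <- a[keep]; bk <- b[keep]
        Ai <- matrix(ak, length(keep), length(keep))
        Bi <- matrix(bk, length(keep), length(keep))
        Aj <- t(Ai)
        Bj <- t(Bi)
        cross <- (Ai < Aj) & (Aj < Bi) & (Bi < Bj)
        pr <- which(cross, arr.ind = TRUE)
        if (nrow(pr) > 0L) {
            cyc <- bp$greyCycle[keep]
            edges <- rbind(cyc[pr[, 1L]], cyc[pr[, 2L]])
            g <- igraph::make_graph(edges = as.vector(edges), n = ncyc,
                                    directed = FALSE)
            memb <- igraph::components(g)$membership
        }
    }

    ## per-component statistics
    comps <- sort(unique(memb))
    memb <- match(memb, comps)
    ncomp <- length(comps)
    compOriented <- .by_group(orientedCycle, memb, ncomp, any)
    compLen <- as.integer(.by_group(lens, memb, ncomp, sum))
    ## span over all member points (black edges cover every cycle point)
    pu <- bp$pos[bp$blackU + 1L]
    pv <- bp$pos[bp$blackV + 1L]
    cmemb <- memb[bp$blackCycle]
    spanS <- as.integer(pmin(.by_group(pu, cmemb, ncomp, min),
                             .by_group(pv, cmemb, ncomp, min)))
    spanE <- as.integer(pmax(.by_group(pu, cmemb, ncomp, max),
                             .by_group(pv, cmemb, ncomp, max)))
    unor <- !compOriented & compLen > 1L
    if (!any(unor)) return(c(0L, 0L))
    s <- spanS[unor]
    e <- spanE[unor]
    hflag <- .hurdle_flags(s, e)
    h <- sum(hflag)
    fortress <- 0L
    if (h > 0L && h %% 2L == 1L) {
        super <- .super_flags(s, e, hflag)
        if (all(super[hflag])) fortress <- 1L
    }
    c(as.integer(h), fortress)
}

## Hurdle flags among unoriented components with spans [s, e].
## A component separates two others iff it has unoriented components both
## strictly inside and not inside its span; hurdles are the non-separating
## ones (minimal components, plus a greatest component containing all
## others).
.hurdle_flags <- function(s, e) {
    nu <- length(s)
    if (nu == 0L) return(logical(0L))
    flags <- logical(nu)
    for (i in seq_len(nu)) {
        j <- setdiff(seq_len(nu), i)
        inside <- s[j] > s[i] & e[j] < e[i]
        flags[i] <- !(any(inside) && any(!inside))
    }
    flags
}

## Super-hurdle flags: hurdle H is super iff deleting it turns some
## non-hurdle unoriented component into a hurdle.
.super_flags <- function(s, e, hflag) {
    nu <- length(s)
    super <- logical(nu)
    for (i in which(hflag)) {
        keep <- setdiff(seq_len(nu), i)
        if (length(keep) == 0L) next
        newflags <- .hurdle_flags(s[keep], e[keep])
        old <- hflag[keep]
        if (any(newflags & !old)) super[i] <- TRUE
    }
    super
}

#' Build the breakpoint graph of two genomes
#'
#' When `q` is supplied the pair is first reduced with [relabel()] so the
#' graph is always built against the identity; all distances here are
#' left-invariant, so this loses nothing.
#'
#' @param p A [SignedPermutation-class].
#' @param q Optional second [SignedPermutation-class] (default: identity).
#' @return A [BreakpointGraph-class].
#' @examples
#' bp <- buildBreakpointGraph(SignedPermutation(c(-3L, -2L, -1L)))
#' countCycles(bp)
#' @export
buildBreakpointGraph <- function(p, q = NULL) {
    stopifnot(is(p, "SignedPermutation"))
    g <- p@genes
    if (!is.null(q)) {
        stopifnot(is(q, "SignedPermutation"))
        if (length(q@genes) != length(g))
            stop("p and q must have the same number of genes")
        g <- .relabel_vec(g, q@genes)
    }
    bp <- .bp_build(g)
    new("BreakpointGraph", n = bp$n, points = bp$pts,
        blackEdges = cbind(bp$blackU, bp$blackV, deparse.level = 0L),
        greyEdges = cbind(2L * (seq_len(bp$n + 1L) - 1L),
                          2L * (seq_len(bp$n + 1L) - 1L) + 1L,
                          deparse.level = 0L),
        blackCycle = bp$blackCycle, greyCycle = bp$greyCycle,
        blackXi = bp$blackXi, greyXi = bp$greyXi,
        cycleLengths = bp$cycleLengths)
}

#' @describeIn countCycles number of alternating cycles of a breakpoint
#'   graph
#' @export
setMethod("countCycles", "BreakpointGraph",
    function(x) length(x@cycleLengths))

#' @describeIn numGenes gene count of a breakpoint graph
#' @export
setMethod("numGenes", "BreakpointGraph", function(x) x@n)

#' @describeIn edgeOrientations orientation labels of a breakpoint graph
#' @export
setMethod("edgeOrientations", "BreakpointGraph",
    function(x) list(black = x@blackXi, grey = x@greyXi))

#' @describeIn classifyCycles cycle table of a breakpoint graph
#' @export
setMethod("classifyCycles", "BreakpointGraph", function(x) {
    ncyc <- length(x@cycleLengths)
    posOr <- .by_group(x@blackXi > 0L, x@blackCycle, ncyc, any)
    negOr <- .by_group(x@blackXi < 0L, x@blackCycle, ncyc, any)
    data.frame(cycle = seq_len(ncyc),
               length = x@cycleLengths,
               oriented = posOr & negOr)
})

## rebuild the internal list view from the S4 slots
.bp_from_s4 <- function(x) {
    np <- 2L * x@n + 2L
    pos <- integer(np)
    pos[x@points + 1L] <- seq_len(np)
    list(n = x@n, pts = x@points, pos = pos,
         blackU = x@blackEdges[, 1L], blackV = x@blackEdges[, 2L],
         blackCycle = x@blackCycle, blackXi = x@blackXi,
         greyCycle = x@greyCycle, greyXi = x@greyXi,
         cycleLengths = x@cycleLengths, ncyc = length(x@cycleLengths))
}

#' @describeIn componentsHurdles components/hurdles of a breakpoint graph
#' @export
setMethod("componentsHurdles", "BreakpointGraph", function(x) {
    bp <- .bp_from_s4(x)
    n <- bp$n
    ncyc <- bp$ncyc
    posOr <- .by_group(bp$blackXi > 0L, bp$blackCycle, ncyc, any)
    negOr <- .by_group(bp$blackXi < 0L, bp$blackCycle, ncyc, any)
    orientedCycle <- posOr & negOr

    m <- n + 1L
    gidx <- seq_len(m)
    p1 <- bp$pos[2L * (gidx - 1L) + 1L]
    p2 <- bp$pos[2L * (gidx - 1L) + 2L]
    a <- pmin(p1, p2)
    b <- pmax(p1, p2)
    keep <- which(b - a > 1L)
    memb <- seq_len(ncyc)
    if (length(keep) > 1L) {
        ak <- a[keep]; bk <- b[keep]
        Ai <- matrix(ak, length(keep), length(keep))
        Bi <- matrix(bk, length(keep), length(keep))
        cross <- (Ai < t(Ai)) & (t(Ai) < Bi) & (Bi < t(Bi))
        pr <- which(cross, arr.ind = TRUE)
        if (nrow(pr) > 0L) {
            cyc <- bp$greyCycle[keep]
            g <- igraph::make_graph(
                edges = as.vector(rbind(cyc[pr[, 1L]], cyc[pr[, 2L]])),
                n = ncyc, directed = FALSE)
            memb <- igraph::components(g)$membership
        }
    }
    comps <- sort(unique(memb))
    memb <- match(memb, comps)
    ncomp <- length(comps)
    compOriented <- .by_group(orientedCycle, memb, ncomp, any)
    compLen <- as.integer(.by_group(bp$cycleLengths, memb, ncomp, sum))
    pu <- bp$pos[bp$blackU + 1L]
    pv <- bp$pos[bp$blackV + 1L]
    cmemb <- memb[bp$blackCycle]
    spanS <- as.integer(pmin(.by_group(pu, cmemb, ncomp, min),
                             .by_group(pv, cmemb, ncomp, min)))
    spanE <- as.integer(pmax(.by_group(pu, cmemb, ncomp, max),
                             .by_group(pv, cmemb, ncomp, max)))
    unor <- !compOriented & compLen > 1L

    hurdle <- logical(ncomp)
    super <- logical(ncomp)
    if (any(unor)) {
        iu <- which(unor)
        hf <- .hurdle_flags(spanS[iu], spanE[iu])
        sf <- .super_flags(spanS[iu], spanE[iu], hf)
        hurdle[iu] <- hf
        super[iu] <- sf
    }
    h <- sum(hurdle)
    fortress <- if (h > 0L && h %% 2L == 1L && all(super[hurdle])) 1L else 0L
    cyclesPerComp <- split(seq_len(ncyc), memb)
    list(components = data.frame(
             component = seq_len(ncomp),
             cycles = I(unname(cyclesPerComp)),
             spanStart = spanS, spanEnd = spanE,
             length = compLen,
             oriented = compOriented,
             unoriented = unor,
             hurdle = hurdle,
             superHurdle = super),
         h = as.integer(h),
         fortress = fortress)
})

setMethod("show", "BreakpointGraph", function(object) {
    cl <- classifyCycles(object)
    cat(sprintf("BreakpointGraph: n = %d, %d black + %d grey edges, %d cycle(s)\n",
                object@n, nrow(object@blackEdges), nrow(object@greyEdges),
                nrow(cl)))
    cat(sprintf("  oriented cycles: %d; trivial (length-1) cycles: %d\n",
                sum(cl$oriented), sum(cl$length == 1L)))
})

#' Dump a breakpoint graph as an edge-list text (debugging aid)
#'
#' Not a stable format; extremities are printed as `g.t`/`g.h` (tail/head
#' of gene `g`; the frame markers are `0.h` and `(n+1).t`).
#'
#' @param x A [BreakpointGraph-class].
#' @param file Connection or path (default: stdout).
#' @return Invisibly, the lines written.
#' @export
dumpBreakpointGraph <- function(x, file = stdout()) {
    stopifnot(is(x, "BreakpointGraph"))
    lab <- function(p) {
        g <- p %/% 2L + p %% 2L   # point 2i-1, 2i -> gene i; 0 -> 0
        side <- ifelse(p %% 2L == 1L, "t", "h")
        side[p == 0L] <- "h"
        g[p == 0L] <- 0L
        paste0(g, ".", side)
    }
    lines <- c(
        sprintf("black\t%s\t%s\tcycle=%d\txi=%+d",
                lab(x@blackEdges[, 1L]), lab(x@blackEdges[, 2L]),
                x@blackCycle, x@blackXi),
        sprintf("grey\t%s\t%s\tcycle=%d\txi=%+d",
                lab(x@greyEdges[, 1L]), lab(x@greyEdges[, 2L]),
                x@greyCycle, x@greyXi))
    writeLines(lines, file)
    invisible(lines)
}
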