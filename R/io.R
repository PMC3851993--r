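## GRIMM-style genome text format.
##
## A record is a header line ">name" followed by one whitespace-separated
## line of signed decimal integers terminated by "$". Exactly one
## chromosome (one "$") per record; "#" starts a comment; UTF-8, LF or
## CRLF line endings.

#' Read genomes from a GRIMM-style file
#'
#' @param file Path, connection, or a character vector of lines (when
#'   `text = TRUE` semantics are wanted pass the text through
#'   [textConnection()]).
#' @return Named list of [SignedPermutation-class] objects; all records
#'   must share the same number of genes.
#' @examples
#' genomes <- readGenomes(textConnection(">g1\n1 -3 2 $"))
#' geneOrder(genomes$g1)
#' @export
readGenomes <- function(file) {
    lines <- readLines(file, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- sub("\r$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    out <- list()
    name <- NULL
    buf <- character()
    flush_record <- function(name, buf, out) {
        if (is.null(name)) stop("genome data found before any '>' header")
        body <- paste(buf, collapse = " ")
        if (!nzchar(trimws(body)))
            stop(sprintf("record '%s' has no gene data", name))
        ndollar <- lengths(regmatches(body, gregexpr("\\$", body)))
        if (ndollar == 0L)
            stop(sprintf(
                "record '%s' is not terminated by '$' (multichromosomal and unterminated records are not supported)",
                name))
        if (ndollar > 1L)
            stop(sprintf(
                "record '%s' has %d chromosomes; only unichromosomal genomes are supported",
                name, ndollar))
        body <- trimws(sub("\\$.*$", "", body))
        toks <- strsplit(body, "[[:space:]]+")[[1]]
        toks <- toks[nzchar(toks)]
        g <- suppressWarnings(as.integer(toks))
        if (anyNA(g) || any(g == 0L))
            stop(sprintf("record '%s' contains non-integer or zero labels",
                         name))
        n <- length(g)
        if (!identical(sort(abs(g)), seq_len(n)))
            stop(sprintf(
                "record '%s': gene labels must be 1..n each once (got %s)",
                name, paste(g, collapse = " ")))
        if (!is.null(out$.n) && out$.n != n)
            stop(sprintf(
                "record '%s' has %d genes but earlier records have %d",
                name, n, out$.n))
        out$.n <- n
        out$genomes[[name]] <- new("SignedPermutation", genes = g)
        out
    }
    acc <- list(genomes = list(), .n = NULL)
    for (ln in lines) {
        if (startsWith(ln, ">")) {
            if (!is.null(name)) acc <- flush_record(name, buf, acc)
            name <- trimws(sub("^>", "", ln))
            if (!nzchar(name)) stop("empty genome name in header line")
            if (name %in% names(acc$genomes))
                stop(sprintf("duplicate genome name '%s'", name))
            buf <- character()
        } else {
            if (is.null(name))
                stop("genome data found before any '>' header")
            buf <- c(buf, ln)
        }
    }
    if (!is.null(name)) acc <- flush_record(name, buf, acc)
    acc$genomes
}

#' Write genomes in the GRIMM-style format
#'
#' @param genomes Named list of [SignedPermutation-class] objects.
#' @param file Path or connection to write to.
#' @return Invisibly, the character vector of lines written.
#' @export
writeGenomes <- function(genomes, file) {
    if (length(genomes) == 0L) {
        writeLines(character(), file)
        return(invisible(character()))
    }
    nms <- names(genomes)
    if (is.null(nms) || any(!nzchar(nms)))
        stop("genomes must be a fully named list")
    lines <- unlist(lapply(seq_along(genomes), function(i) {
        g <- genomes[[i]]
        if (!is(g, "SignedPermutation"))
            stop("all elements must be SignedPermutation objects")
        c(paste0(">", nms[i]),
          paste(c(g@genes, "$"), collapse = " "))
    }))
    writeLines(lines, file)
    invisible(lines)
}
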