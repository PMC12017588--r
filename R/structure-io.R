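## File formats: .dbn structure files, the .st structure-array dialect
## (read-only), and TSV score matrices / long-form pair tables.

#' Read a .dbn dot-bracket file
#'
#' Records are 2- or 3-line blocks: a \code{">name"} line, an optional
#' nucleotide sequence line (letters only), and the bracket line.  A line
#' of letters only is taken as the sequence; a line containing \code{(},
#' \code{)} or \code{.} as the brackets.  Brackets are checked for balance,
#' and pseudoknot bracket characters (\code{[]{}<>} or letters in the
#' bracket line) are rejected.
#'
#' @param path path to a .dbn file.
#' @return A [DotBracketSet-class], record order preserved.
#' @export
readDBN <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    starts <- grep("^>", lines)
    if (!length(starts)) stop("no '>' record headers found in ", path)
    if (starts[1] != 1L)
        stop("content before the first '>' header in ", path)
    ends <- c(starts[-1] - 1L, length(lines))
    nms <- character(0); seqs <- character(0); brks <- character(0)
    for (r in seq_along(starts)) {
        name <- sub("^>\\s*", "", lines[starts[r]])
        body <- lines[seq.int(starts[r] + 1L, length.out =
                              ends[r] - starts[r])]
        if (length(body) < 1L || length(body) > 2L)
            stop("record ", name, ": expected 1 or 2 lines after the ",
                 "header, got ", length(body))
        seq <- NA_character_
        if (length(body) == 2L) {
            if (!grepl("^[A-Za-z]+$", body[1]))
                stop("record ", name, ": expected a sequence line ",
                     "(letters only) before the bracket line")
            seq <- body[1]
            bracket <- body[2]
        } else {
            bracket <- body[1]
        }
        if (grepl("^[A-Za-z]+$", bracket))
            stop("record ", name, ": sequence line present but bracket ",
                 "line missing")
        chk <- .checkBrackets(bracket)
        if (!is.null(chk)) stop("record ", name, ": ", chk)
        if (!is.na(seq) && nchar(seq) != nchar(bracket))
            stop("record ", name, ": sequence length (", nchar(seq),
                 ") != bracket length (", nchar(bracket), ")")
        nms <- c(nms, name); seqs <- c(seqs, seq); brks <- c(brks, bracket)
    }
    new("DotBracketSet", names = nms, brackets = brks, sequence = seqs)
}

#' Write a DotBracketSet to a .dbn file
#'
#' Inverse of [readDBN()]: reading the file back reproduces names,
#' sequences and bracket strings exactly.
#'
#' @param x a [DotBracketSet-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDBN <- function(x, path) {
    stopifnot(is(x, "DotBracketSet"))
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(length(x))) {
        writeLines(paste0(">", x@names[i]), con)
        if (!is.na(x@sequence[i])) writeLines(x@sequence[i], con)
        writeLines(x@brackets[i], con)
    }
    invisible(path)
}

#' Read a bpRNA-style .st file
#'
#' Layout: \code{#}-prefixed header lines, then the sequence line, the
#' dot-bracket line, and the structure-array line (any further segment
#' lines are ignored).  Only the structure-array line is consumed -- the
#' file's own dot-bracket is trusted, not re-annotated -- but it is checked
#' against the eight-letter alphabet, so pseudoknot/G-quadruplex
#' annotations (e.g. \code{K}, \code{G}) are rejected with the offending
#' character and position.
#'
#' @param path path to a .st file.
#' @return A [StructureArraySet-class] of length 1; the name is taken
#'   from the \code{#Name:} header, or the file name stem.
#' @export
readST <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- trimws(readLines(path))
    headers <- lines[startsWith(lines, "#")]
    body <- lines[!startsWith(lines, "#") & nzchar(lines)]
    if (length(body) < 3L)
        stop("malformed .st file ", path, ": expected sequence, ",
             "dot-bracket and structure-array lines, found ", length(body))
    codes <- body[3]
    bad <- .firstBadCode(codes)
    if (!is.null(bad))
        stop("structure-array line of ", path, ": invalid code '",
             bad$char, "' at position ", bad$pos,
             " (pseudoknot/G-quadruplex annotations are unsupported)")
    nm_line <- grep("^#\\s*Name:", headers, value = TRUE)
    name <- if (length(nm_line)) {
        trimws(sub("^#\\s*Name:\\s*", "", nm_line[1]))
    } else {
        sub("\\.[^.]*$", "", basename(path))
    }
    new("StructureArraySet", names = name, codes = codes)
}

#' Write a symmetric score matrix as TSV
#'
#' Header row of ids, first column of ids, values with 6 decimal places;
#' round-trips through [readScoreMatrix()] to 1e-6.
#'
#' @param m square symmetric numeric matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeScoreMatrix <- function(m, path) {
    stopifnot(is.matrix(m))
    if (nrow(m) != ncol(m)) stop("matrix must be square")
    if (max(abs(m - t(m))) > 1e-9) stop("matrix must be symmetric")
    ids <- rownames(m)
    if (is.null(ids)) stop("matrix must carry ids as dimnames")
    df <- data.frame(id = ids, formatC(m, format = "f", digits = 6),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df) <- c("id", ids)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a TSV score matrix written by [writeScoreMatrix()]
#'
#' @param path input path.
#' @return Symmetric numeric matrix with ids as dimnames.
#' @export
readScoreMatrix <- function(path) {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
    if (!identical(colnames(m), ids))
        stop("row and column ids disagree in ", path)
    m
}

#' Write long-form pair scores as TSV
#'
#' Columns \code{id_a}, \code{id_b}, \code{cosine}, \code{penalty},
#' \code{score}, \code{k}, \code{fuzzy} (and \code{max_dist} when
#' present), as produced by [scorePairs()].
#'
#' @param pairs data.frame of pair scores.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePairScores <- function(pairs, path) {
    need <- c("id_a", "id_b", "cosine", "penalty", "score", "k", "fuzzy")
    if (!all(need %in% names(pairs)))
        stop("pair table must have columns ",
             paste(need, collapse = ", "))
    write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
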