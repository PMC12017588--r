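## Dot-bracket parsing and structure-array annotation.
##
## The annotation is the standard loop decomposition of a pseudoknot-free
## secondary structure: paired positions become L ('(') or R (')'), and each
## maximal unpaired run is classified from its innermost enclosing pair:
## no enclosing pair -> E (touches a terminus) or X (strictly between
## stems); enclosing loop with 0 branch helices -> H; 1 branch with unpaired
## positions on one side only -> B, on both sides -> I; >= 2 branches -> M.

PSEUDOKNOT_CHARS <- c("[", "]", "{", "}", "<", ">")

## NULL when valid, otherwise a 1-based diagnostic string.  Used both by the
## DotBracketSet validity method and by the .dbn parser.
.checkBrackets <- function(b) {
    ch <- strsplit(b, "", fixed = TRUE)[[1]]
    pk <- which(ch %in% PSEUDOKNOT_CHARS | grepl("[A-Za-z]", ch))
    if (length(pk))
        return(sprintf(
            "pseudoknots unsupported: bracket character '%s' at position %d",
            ch[pk[1]], pk[1]))
    bad <- which(!ch %in% c("(", ")", "."))
    if (length(bad))
        return(sprintf("invalid character '%s' at position %d",
                       ch[bad[1]], bad[1]))
    depth <- 0L
    open_stack <- integer(0)
    for (i in seq_along(ch)) {
        if (ch[i] == "(") {
            open_stack <- c(open_stack, i)
        } else if (ch[i] == ")") {
            if (length(open_stack) == 0L)
                return(sprintf("unbalanced: unmatched ')' at position %d", i))
            open_stack <- open_stack[-length(open_stack)]
        }
    }
    if (length(open_stack))
        return(sprintf("unbalanced: unmatched '(' at position %d",
                       open_stack[1]))
    NULL
}

## first character outside the 8-letter alphabet, or NULL
.firstBadCode <- function(codes) {
    ch <- strsplit(codes, "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% STRUCT_ALPHABET)
    if (length(bad)) list(char = ch[bad[1]], pos = bad[1]) else NULL
}

#' Base-pair partner table of a dot-bracket structure
#'
#' Stack-based matching of balanced, pseudoknot-free brackets: \code{(} at
#' position i matched to \code{)} at position j gives
#' \code{partner[i] = j} and \code{partner[j] = i}; unpaired positions get
#' 0.  The result is an involution with properly nested pairs.
#'
#' @param brackets a single dot-bracket string, or a
#'   [DotBracketSet-class] of length 1.
#' @return Integer vector of partner positions (0 = unpaired), 1-based.
#' @examples
#' pairTable("(...)")
#' @export
pairTable <- function(brackets) {
    brackets <- .asBracketString(brackets)
    chk <- .checkBrackets(brackets)
    if (!is.null(chk)) stop(chk, call. = FALSE)
    ch <- strsplit(brackets, "", fixed = TRUE)[[1]]
    partner <- integer(length(ch))
    stack <- integer(0)
    for (i in seq_along(ch)) {
        if (ch[i] == "(") {
            stack <- c(stack, i)
        } else if (ch[i] == ")") {
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            partner[i] <- j
            partner[j] <- i
        }
    }
    partner
}

.asBracketString <- function(x) {
    if (is(x, "DotBracketSet")) {
        if (length(x) != 1L)
            stop("expected a single structure")
        x@brackets
    } else {
        stopifnot(is.character(x), length(x) == 1L)
        x
    }
}

#' Annotate one dot-bracket string as a structure array
#'
#' @param brackets a single dot-bracket string.
#' @return Structure-array string of the same length over
#'   [structAlphabet()].
#' @examples
#' annotateStructure("(((...)))")           # "LLLHHHRRR"
#' annotateStructure("(((...))).((...))")   # "LLLHHHRRRXLLHHHRR"
#' @export
annotateStructure <- function(brackets) {
    brackets <- .asBracketString(brackets)
    partner <- pairTable(brackets)
    L <- length(partner)
    ch <- strsplit(brackets, "", fixed = TRUE)[[1]]

    ## innermost enclosing '(' position of every position (0 = none), and
    ## branch count of every loop, collected in one scan
    encl <- integer(L)
    nchild <- integer(L + 1L)  # nchild[i + 1] = branches of loop opened at i
    stack <- integer(0)
    for (i in seq_len(L)) {
        top <- if (length(stack)) stack[length(stack)] else 0L
        if (ch[i] == "(") {
            encl[i] <- top
            nchild[top + 1L] <- nchild[top + 1L] + 1L
            stack <- c(stack, i)
        } else if (ch[i] == ")") {
            stack <- stack[-length(stack)]
            encl[i] <- if (length(stack)) stack[length(stack)] else 0L
        } else {
            encl[i] <- top
        }
    }

    out <- character(L)
    out[ch == "("] <- "L"
    out[ch == ")"] <- "R"

    unp <- which(ch == ".")
    if (length(unp)) {
        ## maximal unpaired runs (cannot span different enclosing pairs)
        run_id <- cumsum(c(1L, diff(unp) != 1L))
        for (r in split(unp, run_id)) {
            i0 <- encl[r[1]]
            if (i0 == 0L) {
                ## exterior: E at the flanks, X strictly between stems
                code <- if (r[1] == 1L || r[length(r)] == L) "E" else "X"
            } else {
                nb <- nchild[i0 + 1L]
                if (nb == 0L) {
                    code <- "H"
                } else if (nb >= 2L) {
                    code <- "M"
                } else {
                    ## one branch helix: B if only one side of the loop has
                    ## unpaired positions, I if both do
                    j0 <- partner[i0]
                    inner <- seq.int(i0 + 1L, j0 - 1L)
                    loop_unp <- inner[ch[inner] == "." & encl[inner] == i0]
                    child_open <- inner[ch[inner] == "(" &
                                        encl[inner] == i0][1]
                    left <- any(loop_unp < child_open)
                    right <- any(loop_unp > partner[child_open])
                    code <- if (left && right) "I" else "B"
                }
            }
            out[r] <- code
        }
    }
    paste(out, collapse = "")
}

#' Annotate a set of dot-bracket structures
#'
#' Converts every structure of a [DotBracketSet-class] into its
#' per-nucleotide structure array.
#'
#' @param x a [DotBracketSet-class].
#' @return A [StructureArraySet-class] with the same names and order.
#' @examples
#' dbs <- DotBracketSet(c(a = "(((...)))", b = "((((....))))"))
#' annotateStructures(dbs)
#' @export
annotateStructures <- function(x) {
    stopifnot(is(x, "DotBracketSet"))
    codes <- vapply(x@brackets, annotateStructure, character(1),
                    USE.NAMES = FALSE)
    new("StructureArraySet", names = x@names, codes = codes)
}
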