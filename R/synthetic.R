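## Synthetic pseudoknot-free structures and planted-label families.
##
## The generator emulates the shape statistics of mid-size structured RNAs:
## helices with geometric lengths (mean ~3.3 stacked pairs), hairpin loops
## of >= minHairpin unpaired bases, bulges/internal loops of 1-4 bases,
## multiloops with 2-3 branches, and short terminal E runs.  Families are a
## base structure plus members derived by a small number of
## validity-preserving edits, standing in for intra-subclass variation.
## All randomness flows through R's seeded Mersenne-Twister RNG.

#' Synthetic-dataset configuration
#'
#' @param seed RNG seed.
#' @param nFamilies number of planted families (default 5).
#' @param membersPerFamily structures per family (default 6).
#' @param lengthRange c(min, max) base-structure target length in
#'   nucleotides (default 60-140).
#' @param minHairpin minimum unpaired bases of a hairpin loop (default 3,
#'   the sterically shortest loop).
#' @param branchProb probability of branching instead of closing a loop
#'   during recursive generation (default 0.4).
#' @param mutationOps validity-preserving edits per family member
#'   (default 4).
#' @return A [SynthConfig-class].
#' @examples
#' synthConfig(seed = 1)
#' @export
synthConfig <- function(seed = 0, nFamilies = 5, membersPerFamily = 6,
                        lengthRange = c(60, 140), minHairpin = 3,
                        branchProb = 0.4, mutationOps = 4) {
    new("SynthConfig",
        seed = .checkCount(seed, "seed", min = 0L),
        nFamilies = .checkCount(nFamilies, "nFamilies"),
        membersPerFamily = .checkCount(membersPerFamily, "membersPerFamily"),
        lengthRange = as.integer(lengthRange),
        minHairpin = .checkCount(minHairpin, "minHairpin", min = 0L),
        branchProb = as.numeric(branchProb),
        mutationOps = .checkCount(mutationOps, "mutationOps", min = 0L))
}

#' Generate one random pseudoknot-free structure
#'
#' Recursive generation: a helix of geometric length encloses either a
#' hairpin loop, a one-branch loop (bulge or internal loop), or a
#' multiloop with two or three branches, chosen by \code{branchProb} while
#' the length budget allows; top-level stems are flanked by short E runs
#' and occasionally separated by an X run.  Output is always balanced and
#' pseudoknot-free, so [annotateStructure()] never errors on it.
#'
#' @param targetLength approximate structure length (the result's length is
#'   close to but not exactly this).
#' @param minHairpin minimum unpaired bases of a hairpin loop.
#' @param branchProb branching probability in \eqn{[0, 1]}.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return A single dot-bracket string.
#' @examples
#' randomStructure(60, seed = 1)
#' @export
randomStructure <- function(targetLength, minHairpin = 3, branchProb = 0.4,
                            seed = NULL) {
    targetLength <- .checkCount(targetLength, "targetLength",
                                min = as.integer(2L + minHairpin))
    gen <- function() {
        e_left <- sample(0:4, 1)
        e_right <- sample(0:4, 1)
        budget <- targetLength - e_left - e_right
        stem_min <- 2L + minHairpin
        if (budget < stem_min) budget <- stem_min
        ## occasionally two top-level stems separated by an X run
        two_stems <- budget >= 2L * stem_min + 2L && runif(1) < 0.3
        body <- if (two_stems) {
            xrun <- sample(1:3, 1)
            b1 <- round((budget - xrun) * runif(1, 0.35, 0.65))
            b1 <- max(stem_min, min(b1, budget - xrun - stem_min))
            paste0(.genSubtree(b1, minHairpin, branchProb, 1L),
                   strrep(".", xrun),
                   .genSubtree(budget - xrun - b1, minHairpin, branchProb,
                               1L))
        } else {
            .genSubtree(budget, minHairpin, branchProb, 1L)
        }
        paste0(strrep(".", e_left), body, strrep(".", e_right))
    }
    if (is.null(seed)) gen() else .withSeed(seed, gen())
}

## One helix-rooted subtree consuming at most `budget` characters.
.genSubtree <- function(budget, minH, branchProb, depth) {
    stem_min <- 2L + minH
    h <- 1L + rgeom(1, 0.3)                       # helix length, mean ~3.3
    h <- max(1L, min(h, (budget - minH) %/% 2L))
    inner <- budget - 2L * h
    can1 <- inner >= stem_min + 1L
    can2 <- inner >= 2L * stem_min + 3L
    ## keep spending the budget: close with a hairpin only when the
    ## interior is nearly exhausted (or rarely, for shape diversity);
    ## branchProb sets the multiloop rate, otherwise the stem continues
    ## through a bulge/internal loop
    nb <- if (!can1 || depth >= 30L ||
              (inner <= 4L * stem_min && runif(1) < 0.05)) 0L
          else if (can2 && runif(1) < branchProb) 2L
          else 1L
    if (nb == 0L) {
        ## hairpin: spend most of the interior, keep loops modest
        loop <- min(inner, minH + rgeom(1, 0.4))
        interior <- strrep(".", max(minH, loop))
    } else if (nb == 1L) {
        ## bulge (one-sided) or internal loop (two-sided)
        sides <- if (runif(1) < 0.4) c(sample(1:3, 1), 0L)
                 else c(sample(1:2, 1), sample(1:2, 1))
        if (runif(1) < 0.5) sides <- rev(sides)
        while (inner - sum(sides) < stem_min)     # keep the child viable
            sides[which.max(sides)] <- sides[which.max(sides)] - 1L
        child <- inner - sum(sides)
        interior <- paste0(strrep(".", sides[1]),
                           .genSubtree(child, minH, branchProb, depth + 1L),
                           strrep(".", sides[2]))
    } else {
        ## multiloop with 2 (sometimes 3) branches and 1-3 nt spacers
        nbr <- if (inner >= 3L * stem_min + 4L && runif(1) < 0.3) 3L else 2L
        sp <- sample(1:3, nbr + 1L, replace = TRUE)
        avail <- inner - sum(sp)
        while (avail < nbr * stem_min) {          # shrink spacers if tight
            sp[which.max(sp)] <- sp[which.max(sp)] - 1L
            avail <- inner - sum(sp)
        }
        ## proportional split of the interior budget over the branches
        w <- runif(nbr, 0.8, 1.2)
        sizes <- floor(avail * w / sum(w))
        sizes[1] <- avail - sum(sizes[-1])
        sizes <- pmax(sizes, stem_min)
        while (sum(sizes) > avail) {
            i <- which.max(sizes)
            sizes[i] <- sizes[i] - 1L
        }
        pieces <- character(nbr)
        for (i in seq_len(nbr))
            pieces[i] <- .genSubtree(sizes[i], minH, branchProb, depth + 1L)
        interior <- paste0(strrep(".", sp[1]),
                           paste0(pieces, strrep(".", sp[-1]),
                                  collapse = ""))
    }
    paste0(strrep("(", h), interior, strrep(")", h))
}

#' Derive a family of perturbed structures from a base structure
#'
#' Each member is the base after \code{ops} validity-preserving edits drawn
#' from: extend/shrink a helix by one pair, extend/shrink an unpaired run
#' by one base (hairpin loops never shrink below \code{minHairpin}), add a
#' short branch hairpin inside a loop, or remove a lone-pair terminal
#' hairpin.  Impossible edits are resampled (bounded retries), so members
#' always remain valid pseudoknot-free dot-brackets.
#'
#' @param base a dot-bracket string (or [DotBracketSet-class] of
#'   length 1).
#' @param members number of members to derive.
#' @param ops edits per member.
#' @param minHairpin minimum hairpin-loop size to respect when shrinking.
#' @param seed optional seed; when NULL the current RNG stream is used.
#' @return A [DotBracketSet-class] of \code{members} structures.
#' @examples
#' mutateFamily("(((...)))", members = 3, ops = 1, seed = 1)
#' @export
mutateFamily <- function(base, members, ops, minHairpin = 3, seed = NULL) {
    base <- .asBracketString(base)
    members <- .checkCount(members, "members")
    ops <- .checkCount(ops, "ops", min = 0L)
    gen <- function() {
        out <- character(members)
        for (m in seq_len(members)) {
            s <- base
            for (o in seq_len(ops)) s <- .mutateOnce(s, minHairpin)
            out[m] <- s
        }
        out
    }
    brackets <- if (is.null(seed)) gen() else .withSeed(seed, gen())
    DotBracketSet(brackets, names = paste0("member_", seq_len(members)))
}

## one random validity-preserving edit; falls back to loop_extend (always
## possible) after bounded retries
.mutateOnce <- function(s, minH, retries = 20L) {
    for (t in seq_len(retries)) {
        op <- sample(c("helix_extend", "helix_shrink", "loop_extend",
                       "loop_shrink", "branch_add", "branch_remove"), 1)
        res <- switch(op,
            helix_extend = .opHelixExtend(s),
            helix_shrink = .opHelixShrink(s),
            loop_extend = .opLoopExtend(s),
            loop_shrink = .opLoopShrink(s, minH),
            branch_add = .opBranchAdd(s, minH),
            branch_remove = .opBranchRemove(s, minH))
        if (!is.null(res)) return(res)
    }
    .opLoopExtend(s)
}

.insertAt <- function(s, pos, what) {
    ## insert `what` so that it starts at position `pos` (1-based)
    paste0(substr(s, 1, pos - 1L), what, substr(s, pos, nchar(s)))
}

.deleteAt <- function(s, pos) {
    pos <- sort(pos)
    keep <- setdiff(seq_len(nchar(s)), pos)
    paste(strsplit(s, "", fixed = TRUE)[[1]][keep], collapse = "")
}

.opHelixExtend <- function(s) {
    pt <- pairTable(s)
    opens <- which(pt > seq_along(pt))
    if (!length(opens)) return(NULL)
    i <- if (length(opens) == 1L) opens else sample(opens, 1)
    j <- pt[i]
    s <- .insertAt(s, j + 1L, ")")
    .insertAt(s, i, "(")
}

.opHelixShrink <- function(s) {
    pt <- pairTable(s)
    ## stacked pairs only, so a helix never disappears entirely
    opens <- which(pt > seq_along(pt))
    opens <- opens[opens + 1L <= length(pt) & pt[opens + 1L] == pt[opens] - 1L]
    if (!length(opens)) return(NULL)
    i <- if (length(opens) == 1L) opens else sample(opens, 1)
    .deleteAt(s, c(i, pt[i]))
}

.opLoopExtend <- function(s) {
    unp <- which(strsplit(s, "", fixed = TRUE)[[1]] == ".")
    pos <- if (!length(unp)) nchar(s) + 1L
           else if (length(unp) == 1L) unp else sample(unp, 1)
    .insertAt(s, pos, ".")
}

.opLoopShrink <- function(s, minH) {
    ann <- strsplit(annotateStructure(s), "", fixed = TRUE)[[1]]
    unp <- which(!ann %in% c("L", "R"))
    if (!length(unp)) return(NULL)
    ## hairpin runs at the minimum size are off-limits
    ok <- vapply(unp, function(p) {
        if (ann[p] != "H") return(TRUE)
        run <- p
        while (run[1] > 1L && ann[run[1] - 1L] == "H")
            run <- c(run[1] - 1L, run)
        while (run[length(run)] < length(ann) &&
               ann[run[length(run)] + 1L] == "H")
            run <- c(run, run[length(run)] + 1L)
        length(run) > minH
    }, logical(1))
    unp <- unp[ok]
    if (!length(unp)) return(NULL)
    p <- if (length(unp) == 1L) unp else sample(unp, 1)
    .deleteAt(s, p)
}

.opBranchAdd <- function(s, minH) {
    unp <- which(strsplit(s, "", fixed = TRUE)[[1]] == ".")
    if (!length(unp)) return(NULL)
    p <- if (length(unp) == 1L) unp else sample(unp, 1)
    .insertAt(s, p, paste0("(", strrep(".", minH), ")"))
}

.opBranchRemove <- function(s, minH) {
    pt <- pairTable(s)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    opens <- which(pt > seq_along(pt))
    ## innermost enclosing open position of every position (0 = none)
    encl <- integer(length(ch))
    stack <- integer(0)
    for (p in seq_along(ch)) {
        top <- if (length(stack)) stack[length(stack)] else 0L
        if (ch[p] == "(") {
            encl[p] <- top
            stack <- c(stack, p)
        } else if (ch[p] == ")") {
            stack <- stack[-length(stack)]
            encl[p] <- if (length(stack)) stack[length(stack)] else 0L
        } else {
            encl[p] <- top
        }
    }
    ## lone-pair terminal hairpins: interior all unpaired, not stacked;
    ## removal must not leave the parent loop as a too-short hairpin
    cand <- opens[vapply(opens, function(i) {
        j <- pt[i]
        interior <- if (j - i > 1L) seq.int(i + 1L, j - 1L) else integer(0)
        if (!all(pt[interior] == 0L)) return(FALSE)
        if (i > 1L && pt[i - 1L] == j + 1L) return(FALSE)
        if (sum(pt > 0L) <= 2L) return(FALSE)  # keep >= 1 remaining pair
        parent <- encl[i]
        if (parent > 0L) {
            siblings <- any(ch == "(" & encl == parent &
                            seq_along(ch) != i)
            if (!siblings) {
                left_after <- pt[parent] - parent - 1L - (j - i + 1L)
                if (left_after < minH) return(FALSE)
            }
        }
        TRUE
    }, logical(1))]
    if (!length(cand)) return(NULL)
    i <- if (length(cand) == 1L) cand else sample(cand, 1)
    .deleteAt(s, seq.int(i, pt[i]))
}

#' Generate a labeled planted-family dataset
#'
#' Draws \code{nFamilies} independent base structures, expands each into
#' \code{membersPerFamily} perturbed members, and annotates everything.
#' Fully reproducible from the config seed.
#'
#' @param config a [SynthConfig-class] from [synthConfig()].
#' @return List with elements \code{arrays}
#'   ([StructureArraySet-class]), \code{dotbrackets}
#'   ([DotBracketSet-class]) and \code{labels} (named integer family
#'   index per structure).
#' @examples
#' ds <- plantedDataset(synthConfig(seed = 0, nFamilies = 2,
#'                                  membersPerFamily = 3))
#' table(ds$labels)
#' @export
plantedDataset <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    .withSeed(config@seed, {
        all_brackets <- character(0)
        all_names <- character(0)
        labels <- integer(0)
        for (f in seq_len(config@nFamilies)) {
            len <- sample(seq.int(config@lengthRange[1],
                                  config@lengthRange[2]), 1)
            base <- randomStructure(len, minHairpin = config@minHairpin,
                                    branchProb = config@branchProb)
            fam <- mutateFamily(base, members = config@membersPerFamily,
                                ops = config@mutationOps,
                                minHairpin = config@minHairpin)
            nms <- sprintf("family%d_member%d", f,
                           seq_len(config@membersPerFamily))
            all_brackets <- c(all_brackets, dotBrackets(fam))
            all_names <- c(all_names, nms)
            labels <- c(labels, rep(f, config@membersPerFamily))
        }
        dbs <- DotBracketSet(unname(all_brackets), names = all_names)
        list(arrays = annotateStructures(dbs), dotbrackets = dbs,
             labels = stats::setNames(as.integer(labels), all_names))
    })
}
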