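## Duplex construction, parsing, serialization and base-pair classification.

PAIR_LEVELS <- c("WC_AU", "WC_UA", "WC_GC", "WC_CG", "WOBBLE_GU",
                 "PSI_A", "PSI_G", "PSI_U", "PSI_C", "MISMATCH",
                 "DANGLING_5", "DANGLING_3")

## category of one aligned (top, bottom) residue pair
pairCategory <- function(top, bottom) {
  key <- paste0(top, bottom)
  switch(key,
    AU = "WC_AU", UA = "WC_UA", GC = "WC_GC", CG = "WC_CG",
    GU = , UG = "WOBBLE_GU",
    PA = , AP = "PSI_A", PG = , GP = "PSI_G",
    PU = , UP = "PSI_U", PC = , CP = "PSI_C",
    "MISMATCH")
}

splitResidues <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}

#' Construct a Duplex
#'
#' @param top top strand, 5'-to-3' (string or character vector of codes).
#' @param bottom bottom strand, 3'-to-5', aligned under the top strand.
#' @param topOffset,bottomOffset number of unpaired leading residues at the
#'   left (5'-top) end of each strand, or `NA` (default) to choose the
#'   alignment automatically by minimizing the number of mismatched pairs.
#' @return A [Duplex-class] object.
#' @examples
#' d <- duplex("UCAGPCAGU", "AGUCAGUCA")
#' classifyPairs(d)
#' @export
duplex <- function(top, bottom, topOffset = NA, bottomOffset = NA) {
  top <- splitResidues(top); bottom <- splitResidues(bottom)
  bad <- setdiff(unique(c(top, bottom)), ALPHABET)
  if (length(bad))
    stop("illegal residue code(s): ", paste(bad, collapse = ", "),
         " (alphabet is A, C, G, U, P)")
  if (is.na(topOffset) || is.na(bottomOffset)) {
    off <- chooseAlignment(top, bottom)
    topOffset <- off[1]; bottomOffset <- off[2]
  }
  new("Duplex", top = top, bottom = bottom,
      topOffset = as.integer(topOffset), bottomOffset = as.integer(bottomOffset))
}

## enumerate feasible single-overhang alignments, pick the one with the
## fewest MISMATCH pairs (ties: more pairs, then 5'-top overhang first)
chooseAlignment <- function(top, bottom) {
  lt <- length(top); lb <- length(bottom)
  cand <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L))
  best <- NULL; bestScore <- NULL
  for (off in cand) {
    np <- min(lt - off[1], lb - off[2])
    if (np < 1L) next
    rt <- lt - off[1] - np; rb <- lb - off[2] - np
    if (rt > 1L || rb > 1L || (rt > 0L && rb > 0L)) next
    ti <- top[seq(off[1] + 1L, off[1] + np)]
    bi <- bottom[seq(off[2] + 1L, off[2] + np)]
    mm <- sum(vapply(seq_len(np),
                     function(i) pairCategory(ti[i], bi[i]) == "MISMATCH", TRUE))
    score <- c(mm, -np)
    if (is.null(best) || score[1] < bestScore[1] ||
        (score[1] == bestScore[1] && score[2] < bestScore[2])) {
      best <- off; bestScore <- score
    }
  }
  if (is.null(best))
    stop("irreconcilable strand lengths: no alignment with single-nucleotide overhangs")
  best
}

#' Parse a two-line duplex string
#'
#' The text format mirrors the conventional visual notation: two lines, the
#' top strand written 5'-to-3' and the bottom strand 3'-to-5', with
#' optional `5'`/`3'` end markers (ASCII or typographic primes) and
#' whitespace. Pseudouridine may be written `P` or the Greek letter Psi.
#' Overhang placement is inferred by aligning the strands so that the
#' number of mismatched pairs is minimal.
#'
#' @param text a single string with two lines, or a character vector of two
#'   lines.
#' @return A [Duplex-class] object.
#' @examples
#' parseDuplex("5' PCAGUCAGU 3'\n3'  GUCAGUCA 5'")
#' @export
parseDuplex <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n")[[1]] else text
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 2L)
    stop("expected exactly two strand lines, got ", length(lines))
  clean <- function(x) {
    x <- gsub("[53]['′ʹ]", "", x)     # end markers 5'/3'
    x <- gsub("Ψ|ψ", "P", x)           # Greek Psi -> P
    x <- gsub("[[:space:]-]", "", x)
    x
  }
  duplex(clean(lines[1]), clean(lines[2]))
}

#' Number of aligned base pairs
#' @param d a [Duplex-class].
#' @return integer count of paired positions (overhangs excluded).
#' @export
pairCount <- function(d) {
  min(length(d@top) - d@topOffset, length(d@bottom) - d@bottomOffset)
}

#' @describeIn duplex top strand as a 5'-to-3' string.
#' @param d a [Duplex-class].
#' @export
topStrand <- function(d) paste(d@top, collapse = "")

#' @describeIn duplex bottom strand as a 3'-to-5' string.
#' @export
bottomStrand <- function(d) paste(d@bottom, collapse = "")

setMethod("show", "Duplex", function(object) {
  cat(formatDuplex(object), "\n")
})

#' Serialize a duplex to the two-line text notation
#'
#' Inverse of [parseDuplex()]: pseudouridine is emitted as `P`, overhangs
#' are shown by space padding.
#'
#' @param d a [Duplex-class].
#' @return A single string with two newline-separated lines.
#' @export
formatDuplex <- function(d) {
  padT <- strrep(" ", d@bottomOffset)
  padB <- strrep(" ", d@topOffset)
  rt <- length(d@top) - d@topOffset - pairCount(d)
  rb <- length(d@bottom) - d@bottomOffset - pairCount(d)
  paste0("5' ", padT, topStrand(d), strrep(" ", rb), " 3'\n",
         "3' ", padB, bottomStrand(d), strrep(" ", rt), " 5'")
}

#' Rotate a duplex (read the same molecule from the other strand)
#'
#' Swaps the strands and reverses each, so the old bottom strand (read
#' 5'-to-3') becomes the new top. An involution: applying it twice returns
#' the original object. All physical quantities (pair-class multiset,
#' nearest-neighbor free energy) are invariant under it.
#'
#' @param d a [Duplex-class].
#' @return The rotated [Duplex-class].
#' @export
reverseDuplex <- function(d) {
  np <- pairCount(d)
  rt <- length(d@top) - d@topOffset - np
  rb <- length(d@bottom) - d@bottomOffset - np
  new("Duplex", top = rev(d@bottom), bottom = rev(d@top),
      topOffset = as.integer(rb), bottomOffset = as.integer(rt))
}

#' Classify every aligned position of a duplex
#'
#' Returns one row per alignment column: Watson-Crick categories
#' (`WC_AU`, `WC_UA`, `WC_GC`, `WC_CG`, named by the top-strand residue
#' first), `WOBBLE_GU` for either orientation of a G-U wobble, `PSI_*` for
#' pairs involving pseudouridine (named by the partner base), `MISMATCH`,
#' and `DANGLING_5`/`DANGLING_3` for single unpaired terminal nucleotides
#' (the suffix is the end of the *dangling nucleotide's own strand*).
#'
#' @param d a [Duplex-class].
#' @return A data.frame with columns `position`, `top`, `bottom`,
#'   `category`. Dangling rows carry `NA` for the absent partner.
#' @export
classifyPairs <- function(d) {
  np <- pairCount(d)
  rt <- length(d@top) - d@topOffset - np
  rb <- length(d@bottom) - d@bottomOffset - np
  rows <- list()
  pos <- 1L
  if (d@topOffset > 0L) {     # top overhang, left end = top strand's 5' end
    rows[[length(rows) + 1L]] <- data.frame(position = pos, top = d@top[1],
      bottom = NA_character_, category = "DANGLING_5")
    pos <- pos + 1L
  }
  if (d@bottomOffset > 0L) {  # bottom overhang at left end = bottom 3' end
    rows[[length(rows) + 1L]] <- data.frame(position = pos, top = NA_character_,
      bottom = d@bottom[1], category = "DANGLING_3")
    pos <- pos + 1L
  }
  for (i in seq_len(np)) {
    t <- d@top[d@topOffset + i]; b <- d@bottom[d@bottomOffset + i]
    rows[[length(rows) + 1L]] <- data.frame(position = pos, top = t, bottom = b,
      category = pairCategory(t, b))
    pos <- pos + 1L
  }
  if (rt > 0L) {              # top overhang, right end = top strand's 3' end
    rows[[length(rows) + 1L]] <- data.frame(position = pos,
      top = d@top[length(d@top)], bottom = NA_character_, category = "DANGLING_3")
    pos <- pos + 1L
  }
  if (rb > 0L) {              # bottom overhang at right end = bottom 5' end
    rows[[length(rows) + 1L]] <- data.frame(position = pos, top = NA_character_,
      bottom = d@bottom[length(d@bottom)], category = "DANGLING_5")
  }
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = PAIR_LEVELS)
  rownames(out) <- NULL
  out
}
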