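## Nearest-neighbor parameter tables: canonical keying, loading, access.

#' Canonical (rotation-normalized) nearest-neighbor stack key
#'
#' A dinucleotide stack is written `"XY/WZ"`: top dinucleotide 5'-to-3',
#' bottom dinucleotide 3'-to-5' (X pairs W, Y pairs Z). Reading the same
#' stack from the other strand (180-degree rotation) gives `"ZW/YX"`;
#' the canonical key is the lexicographically smaller of the two, so each
#' physical stack has exactly one key. Example: `"UC/AG"` and `"GA/CU"`
#' are the same stack, canonically `"GA/CU"`.
#'
#' @param key a stack key string `"XY/WZ"` in either orientation.
#' @return The canonical key string.
#' @export
canonicalStackKey <- function(key) {
  ch <- strsplit(key, "")[[1]]
  if (length(ch) != 5L || ch[3] != "/")
    stop("malformed stack key: ", key)
  rot <- paste0(ch[5], ch[4], "/", ch[2], ch[1])
  if (rot < key) rot else key
}

## stack key for adjacent pairs (t1,b1),(t2,b2), already canonicalized
stackKeyOf <- function(t1, t2, b1, b2) canonicalStackKey(paste0(t1, t2, "/", b1, b2))

## dangle keys are always expressed with the unpaired base on the top
## strand: "d5:X:AB" = X dangling 5' of top residue A (paired to B),
## "d3:X:AB" = X dangling 3' of top residue A. Bottom-strand dangles are
## rotated into this form before lookup.
dangleKey <- function(end, base, pairTop, pairBottom) {
  paste0("d", end, ":", base, ":", pairTop, pairBottom)
}

penaltyCategory <- function(category) {
  switch(as.character(category),
    WC_AU = , WC_UA = "AU",
    WOBBLE_GU = "GU",
    PSI_A = "PA",
    NA_character_)
}

#' Load a nearest-neighbor parameter set from a TSV table
#'
#' The table has columns `type` (`stack`, `initiation`, `terminal`,
#' `dangle5`, `dangle3`), `key`, `dG37` (kcal/mol) and `citation`. Stack
#' keys may be written in either orientation; they are canonicalized on
#' load and duplicates (two orientations of one stack) are an error.
#'
#' @param path path to the TSV file.
#' @return An [NNParameterSet-class].
#' @seealso [defaultNNParams()] for the shipped table.
#' @export
loadNNParams <- function(path) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("type", "key", "dG37", "citation")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  stacks <- numeric(0); dangling <- numeric(0)
  terminal <- numeric(0); initiation <- NA_real_
  prov <- character(0)
  for (i in seq_len(nrow(tab))) {
    ty <- tab$type[i]; val <- tab$dG37[i]; cit <- tab$citation[i]
    if (ty == "stack") {
      k <- canonicalStackKey(tab$key[i])
      if (k %in% names(stacks))
        stop("duplicate stack key (after canonicalization): ", k)
      stacks[k] <- val; prov[k] <- cit
    } else if (ty == "initiation") {
      initiation <- val; prov["initiation"] <- cit
    } else if (ty == "terminal") {
      terminal[tab$key[i]] <- val; prov[paste0("terminal:", tab$key[i])] <- cit
    } else if (ty %in% c("dangle5", "dangle3")) {
      parts <- strsplit(tab$key[i], ":")[[1]]  # "X:AB"
      k <- dangleKey(substring(ty, 7), parts[1],
                     substring(parts[2], 1, 1), substring(parts[2], 2, 2))
      dangling[k] <- val; prov[k] <- cit
    } else stop("unknown parameter type: ", ty)
  }
  if (is.na(initiation)) stop("parameter table lacks an initiation entry")
  new("NNParameterSet", stacks = stacks, initiation = initiation,
      terminalPenalties = terminal, dangling = dangling, provenance = prov)
}

#' Default nearest-neighbor parameter set
#'
#' Loads the parameter table shipped with the package
#' (`extdata/nn_parameters.tsv`): the Watson-Crick stack, initiation and
#' terminal A-U penalty values of Xia et al. (1998); G-U wobble stacks
#' from the Turner 2004 compilation, with the two terminal-addition
#' motifs `5'UC/3'GG` and `5'GU/3'CG` at their revised (Chen & Turner
#' 2012 lineage) values; the published pseudouridine-adenosine stacks and
#' terminal penalty (Hudson, Dean & Znosko 2013 lineage) for the four
#' contexts that are pinned down in the primary literature; and Turner
#' 2004 single dangling-end terms. Each entry carries its citation tag.
#'
#' Pseudouridine contexts other than Psi-A (internal Psi-G, Psi-U, Psi-C,
#' dangling Psi) have no published nearest-neighbor parameters and
#' deliberately raise an "unparameterized context" error in
#' [predictDG37()].
#'
#' @return An [NNParameterSet-class].
#' @export
defaultNNParams <- function() {
  loadNNParams(system.file("extdata", "nn_parameters.tsv",
                           package = "psithermo", mustWork = TRUE))
}

setMethod("show", "NNParameterSet", function(object) {
  cat(sprintf(
    "NNParameterSet: %d stacks, initiation %+0.2f, %d terminal penalties, %d dangling terms\n",
    length(object@stacks), object@initiation,
    length(object@terminalPenalties), length(object@dangling)))
  cat("citations:", paste(sort(unique(object@provenance)), collapse = ", "), "\n")
})

#' @describeIn loadNNParams look up one stack energy (kcal/mol) by key in
#'   either orientation; errors on an unparameterized context.
#' @param params an [NNParameterSet-class].
#' @param key a stack key.
#' @export
stackEnergy <- function(params, key) {
  k <- canonicalStackKey(key)
  if (!k %in% names(params@stacks))
    stop("unparameterized context: stack ", k)
  unname(params@stacks[k])
}

## terminal penalty for a pair category (0 for G-C, error never raised)
terminalPenalty <- function(params, category) {
  pc <- penaltyCategory(category)
  if (is.na(pc)) return(0)
  if (!pc %in% names(params@terminalPenalties)) return(0)
  unname(params@terminalPenalties[pc])
}
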