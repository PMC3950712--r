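## Nearest-neighbor free-energy prediction for a whole duplex, and the
## predicted increment for a terminal-pair addition.

#' Predict the duplex formation free energy at 37 C
#'
#' Sums dinucleotide stack terms over adjacent paired positions, helix
#' initiation, terminal-pair penalties (A-U, G-U and Psi-A ends; G-C ends
#' carry none) and single dangling-end terms. Pairs must be Watson-Crick,
#' G-U wobble or Psi-A; any other context (internal Psi-G/Psi-U/Psi-C,
#' mismatches, dangling Psi) has no published parameter and raises an
#' "unparameterized context" error naming the missing key.
#'
#' The result is invariant under [reverseDuplex()] (180-degree rotation).
#'
#' @param d a [Duplex-class].
#' @param params an [NNParameterSet-class], default [defaultNNParams()].
#' @return An [NNPrediction-class]: total energy (an
#'   [EnergyWithSD-class] with sd 0; parameter tables carry no
#'   uncertainties) plus a per-term breakdown with provenance.
#' @examples
#' p <- defaultNNParams()
#' predictDG37(parseDuplex("UCAGUCAGU\nAGUCAGUCA"), p)
#' @export
predictDG37 <- function(d, params = defaultNNParams()) {
  cls <- classifyPairs(d)
  paired <- cls[!cls$category %in% c("DANGLING_5", "DANGLING_3"), ]
  bad <- !paired$category %in% c("WC_AU", "WC_UA", "WC_GC", "WC_CG",
                                 "WOBBLE_GU", "PSI_A")
  if (any(bad)) {
    b <- paired[which(bad)[1], ]
    stop("unparameterized context: ", b$category, " pair (",
         b$top, "-", b$bottom, ") at position ", b$position)
  }
  rows <- list()
  add <- function(term, key, value, citation)
    rows[[length(rows) + 1L]] <<- data.frame(term = term, key = key,
      dG37 = value, citation = citation, stringsAsFactors = FALSE)

  add("initiation", "init", params@initiation, params@provenance[["initiation"]])

  np <- nrow(paired)
  for (i in seq_len(np - 1L)) {
    k <- stackKeyOf(paired$top[i], paired$top[i + 1L],
                    paired$bottom[i], paired$bottom[i + 1L])
    add("stack", k, stackEnergy(params, k), params@provenance[[k]])
  }

  for (i in c(1L, if (np > 1L) np)) {
    cat. <- penaltyCategory(paired$category[i])
    if (!is.na(cat.)) {
      pen <- terminalPenalty(params, paired$category[i])
      add("terminal", paste0("terminal:", cat.), pen,
          params@provenance[[paste0("terminal:", cat.)]])
    }
  }

  ## dangling ends: rotate bottom-strand dangles onto the top strand
  dang <- cls[cls$category %in% c("DANGLING_5", "DANGLING_3"), ]
  if (nrow(dang)) {
    first <- paired[1L, ]; last <- paired[np, ]
    for (i in seq_len(nrow(dang))) {
      dg <- dang[i, ]
      left <- dg$position < first$position
      if (!is.na(dg$top)) {       # top-strand dangle
        k <- if (left) dangleKey("5", dg$top, first$top, first$bottom)
             else      dangleKey("3", dg$top, last$top, last$bottom)
      } else {                    # bottom-strand dangle, rotated view
        k <- if (left) dangleKey("3", dg$bottom, first$bottom, first$top)
             else      dangleKey("5", dg$bottom, last$bottom, last$top)
      }
      if (!k %in% names(params@dangling))
        stop("unparameterized context: dangling end ", k)
      add("dangle", k, unname(params@dangling[k]), params@provenance[[k]])
    }
  }

  breakdown <- do.call(rbind, rows)
  new("NNPrediction", energy = energyWithSD(sum(breakdown$dG37), 0),
      breakdown = breakdown)
}

setMethod("show", "NNPrediction", function(object) {
  cat(sprintf("NN prediction: dG37 = %.2f kcal/mol\n", object@energy@value))
  print(object@breakdown, row.names = FALSE)
})

#' @describeIn predictDG37 per-term breakdown data.frame.
#' @param x an [NNPrediction-class].
#' @export
breakdown <- function(x) x@breakdown

#' Nearest-neighbor-predicted increment for a terminal-pair addition
#'
#' The expected change in duplex formation free energy on extending a
#' helix by one terminal base pair: the new stack term, plus the terminal
#' penalty of the new terminal pair, minus the penalty of the pair that
#' was terminal before the addition. With the shipped tables this
#' reproduces the classic sums, e.g. adding a 5'-terminal U-A pair in the
#' `5'UC/3'AG` context gives -2.35 + 0.45 = -1.90 kcal/mol, and a
#' 5'-terminal Psi-A pair in `5'PC/3'AG` gives -2.49 + 0.31 = -2.18.
#'
#' @param context the stack key created by the addition, written with the
#'   added pair on the outside, e.g. `"UC/AG"` for a 5' addition (added
#'   pair = first column) or `"GU/CA"` for a 3' addition with `end = "3"`.
#' @param params an [NNParameterSet-class].
#' @param end which end is extended: `"5"` (default) or `"3"`; determines
#'   which column of `context` is the added pair.
#' @param previous pair category previously at the terminus: `"GC"`
#'   (default, no penalty), `"AU"`, `"GU"` or `"PA"`.
#' @return An [EnergyWithSD-class] (sd 0).
#' @export
predictedTerminalIncrement <- function(context, params = defaultNNParams(),
                                       end = c("5", "3"), previous = "GC") {
  end <- match.arg(end)
  ch <- strsplit(context, "")[[1]]
  if (length(ch) != 5L || ch[3] != "/") stop("malformed stack key: ", context)
  newPair <- if (end == "5") c(ch[1], ch[4]) else c(ch[2], ch[5])
  newCat <- pairCategory(newPair[1], newPair[2])
  if (newCat == "MISMATCH")
    stop("added terminal pair ", newPair[1], "-", newPair[2], " is not a pair")
  stack <- stackEnergy(params, context)
  penNew <- terminalPenalty(params, newCat)
  penOld <- if (identical(previous, "GC")) 0 else {
    if (!previous %in% names(params@terminalPenalties))
      stop("unknown previous terminal category: ", previous)
    unname(params@terminalPenalties[previous])
  }
  energyWithSD(stack + penNew - penOld, 0)
}
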