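## S4 class definitions. Validity functions enforce the structural
## invariants; constructors live next to the class they build.

ALPHABET <- c("A", "C", "G", "U", "P")

#' Free energy with a standard deviation
#'
#' A scalar free energy (kcal/mol, formation convention: negative values
#' are stabilizing) together with its standard deviation.
#'
#' @slot value numeric scalar, kcal/mol.
#' @slot sd non-negative numeric scalar, kcal/mol.
#' @export
setClass("EnergyWithSD", representation(value = "numeric", sd = "numeric"),
  validity = function(object) {
    if (length(object@value) != 1L || length(object@sd) != 1L)
      return("value and sd must be scalars")
    if (!is.finite(object@value)) return("value must be finite")
    if (is.na(object@sd) || object@sd < 0) return("sd must be >= 0")
    TRUE
  })

#' @param value numeric scalar, kcal/mol (formation convention).
#' @param sd non-negative standard deviation, kcal/mol.
#' @return An [EnergyWithSD-class] object.
#' @rdname EnergyWithSD-class
#' @export
energyWithSD <- function(value, sd = 0) {
  new("EnergyWithSD", value = as.numeric(value), sd = as.numeric(sd))
}

#' @describeIn EnergyWithSD-class numeric value (kcal/mol).
#' @param object,x an `EnergyWithSD`.
#' @export
setGeneric("energyValue", function(x) standardGeneric("energyValue"))
#' @rdname EnergyWithSD-class
#' @export
setMethod("energyValue", "EnergyWithSD", function(x) x@value)

#' @describeIn EnergyWithSD-class standard deviation (kcal/mol).
#' @export
setGeneric("energySD", function(x) standardGeneric("energySD"))
#' @rdname EnergyWithSD-class
#' @export
setMethod("energySD", "EnergyWithSD", function(x) x@sd)

setMethod("show", "EnergyWithSD", function(object) {
  cat(sprintf("%.2f +/- %.2f kcal/mol\n", object@value, object@sd))
})

#' Aligned antiparallel RNA duplex with optional single-nucleotide overhangs
#'
#' The top strand is stored 5'-to-3', the bottom strand 3'-to-5', so that
#' aligned position i of the top pairs with aligned position i of the
#' bottom. `topOffset`/`bottomOffset` count unpaired leading residues at
#' the left (5'-top) end; right-end overhangs follow from the lengths. At
#' most one unpaired overhang per duplex end is allowed (single dangling
#' ends), and no end may have overhangs on both strands.
#'
#' Pseudouridine is written `P` ("Ψ" is accepted on input by
#' [parseDuplex()]).
#'
#' @slot top character vector of residue codes, 5'-to-3'.
#' @slot bottom character vector of residue codes, 3'-to-5'.
#' @slot topOffset integer, unpaired top residues at the left end (0 or 1).
#' @slot bottomOffset integer, unpaired bottom residues at the left end.
#' @export
setClass("Duplex",
  representation(top = "character", bottom = "character",
                 topOffset = "integer", bottomOffset = "integer"),
  validity = function(object) {
    if (length(object@top) < 1L || length(object@bottom) < 1L)
      return("both strands must have length >= 1")
    bad <- setdiff(unique(c(object@top, object@bottom)), ALPHABET)
    if (length(bad))
      return(paste0("illegal residue code(s): ", paste(bad, collapse = ", "),
                    " (alphabet is A, C, G, U, P)"))
    to <- object@topOffset; bo <- object@bottomOffset
    if (length(to) != 1L || length(bo) != 1L || is.na(to) || is.na(bo))
      return("offsets must be integer scalars")
    if (to < 0L || to > 1L || bo < 0L || bo > 1L)
      return("overhangs are limited to a single nucleotide per end")
    if (to > 0L && bo > 0L)
      return("both strands cannot overhang the same end")
    np <- min(length(object@top) - to, length(object@bottom) - bo)
    if (np < 1L) return("duplex must contain at least one base pair")
    rt <- length(object@top) - to - np
    rb <- length(object@bottom) - bo - np
    if (rt > 1L || rb > 1L)
      return("irreconcilable strand lengths: overhang longer than one nucleotide")
    if (rt > 0L && rb > 0L)
      return("both strands cannot overhang the same end")
    TRUE
  })

#' Nearest-neighbor free-energy parameter set
#'
#' Keyed tables of dinucleotide stack free energies (canonical,
#' rotation-normalized keys, see [canonicalStackKey()]), helix initiation,
#' terminal-pair penalties (by pair category: `"AU"`, `"GU"`, `"PA"`) and
#' single dangling-end terms, all Delta-G at 37 C in kcal/mol, each entry
#' carrying a citation tag.
#'
#' @slot stacks named numeric, canonical stack key -> kcal/mol.
#' @slot initiation numeric scalar, kcal/mol.
#' @slot terminalPenalties named numeric, pair category -> kcal/mol.
#' @slot dangling named numeric, canonical dangle key -> kcal/mol.
#' @slot provenance named character, citation tag per key (stack and dangle
#'   keys, `"initiation"`, and `terminal:<category>`).
#' @export
setClass("NNParameterSet",
  representation(stacks = "numeric", initiation = "numeric",
                 terminalPenalties = "numeric", dangling = "numeric",
                 provenance = "character"),
  validity = function(object) {
    if (length(object@initiation) != 1L || !is.finite(object@initiation))
      return("initiation must be a finite scalar")
    if (!all(is.finite(object@stacks))) return("all stack energies must be finite")
    if (!all(is.finite(object@dangling))) return("all dangling energies must be finite")
    ks <- names(object@stacks)
    if (is.null(ks) || anyDuplicated(ks)) return("stack keys must be unique and named")
    canon <- vapply(ks, canonicalStackKey, "")
    if (!identical(unname(canon), unname(ks)))
      return("every stack key must be stored in canonical (rotation-normalized) form")
    kd <- names(object@dangling)
    if (length(object@dangling) && (is.null(kd) || anyDuplicated(kd)))
      return("dangling keys must be unique and named")
    tn <- names(object@terminalPenalties)
    need <- c(ks, kd, "initiation",
              if (length(tn)) paste0("terminal:", tn))
    missing <- setdiff(need, names(object@provenance))
    if (length(missing))
      return(paste0("provenance missing for: ", paste(head(missing, 3), collapse = ", ")))
    if (any(!nzchar(object@provenance))) return("provenance tags must be nonempty")
    TRUE
  })

#' Nearest-neighbor prediction with per-term breakdown
#'
#' @slot energy an [EnergyWithSD-class], the total Delta-G 37 (kcal/mol).
#' @slot breakdown data.frame with columns `term`, `key`, `dG37`,
#'   `citation`, one row per additive contribution.
#' @export
setClass("NNPrediction",
  representation(energy = "EnergyWithSD", breakdown = "data.frame"))

#' @rdname EnergyWithSD-class
#' @export
setMethod("energyValue", "NNPrediction", function(x) x@energy@value)

#' Two-state van't Hoff parameters
#'
#' Formation enthalpy (kcal/mol) and entropy (cal/(mol K), "eu"), both
#' negative for a duplex that forms on cooling. The temperature-independent
#' Delta-H / Delta-S pair is the two-state model's entire description of
#' the transition (no heat-capacity term).
#'
#' @slot dH numeric, kcal/mol.
#' @slot dS numeric, eu.
#' @export
setClass("TwoStateParams", representation(dH = "numeric", dS = "numeric"),
  validity = function(object) {
    if (length(object@dH) != 1L || length(object@dS) != 1L)
      return("dH and dS must be scalars")
    if (!is.finite(object@dH) || !is.finite(object@dS))
      return("dH and dS must be finite")
    if (object@dH != 0 && object@dS != 0 && object@dH / object@dS <= 0)
      return("dH and dS must share a sign (enthalpy-entropy compensation)")
    TRUE
  })

#' @param dH formation enthalpy, kcal/mol (negative for duplex formation).
#' @param dS formation entropy, cal/(mol K).
#' @return A [TwoStateParams-class] object.
#' @rdname TwoStateParams-class
#' @export
twoStateParams <- function(dH, dS) new("TwoStateParams", dH = as.numeric(dH), dS = as.numeric(dS))

setMethod("show", "TwoStateParams", function(object) {
  cat(sprintf("TwoStateParams: dH = %.1f kcal/mol, dS = %.1f eu (dG37 = %.2f kcal/mol)\n",
              object@dH, object@dS, object@dH - T37 * object@dS / 1000))
})

#' A single absorbance-versus-temperature melting curve
#'
#' @slot temperature numeric, strictly increasing grid in degrees C.
#' @slot absorbance numeric, same length.
#' @slot ct total single-strand concentration, M.
#' @slot baselines named numeric(4) `(m_ss, b_ss, m_ds, b_ds)`: slopes
#'   (absorbance per degree C) and intercepts of the single-strand and
#'   duplex baselines; `NA` when unknown (experimental data).
#' @export
setClass("MeltCurve",
  representation(temperature = "numeric", absorbance = "numeric",
                 ct = "numeric", baselines = "numeric"),
  validity = function(object) {
    if (length(object@temperature) != length(object@absorbance))
      return("temperature and absorbance must have equal length")
    if (length(object@temperature) < 2L) return("need at least two points")
    if (any(diff(object@temperature) <= 0))
      return("temperature grid must be strictly increasing")
    if (length(object@ct) != 1L || !is.finite(object@ct) || object@ct <= 0)
      return("ct must be a positive scalar")
    if (length(object@baselines) != 4L)
      return("baselines must be numeric(4): m_ss, b_ss, m_ds, b_ds")
    TRUE
  })

#' A set of melting curves, one per strand concentration
#'
#' @slot curves list of [MeltCurve-class] objects.
#' @export
setClass("MeltingDataset", representation(curves = "list"),
  validity = function(object) {
    ok <- vapply(object@curves, is, TRUE, class2 = "MeltCurve")
    if (!all(ok)) return("all elements must be MeltCurve objects")
    TRUE
  })

setMethod("show", "MeltingDataset", function(object) {
  cts <- vapply(object@curves, function(c) c@ct, 0)
  cat(sprintf("MeltingDataset: %d curves, CT %.2g-%.2g M\n",
              length(object@curves), min(cts), max(cts)))
})
setMethod("length", "MeltingDataset", function(x) length(x@curves))
setMethod("[[", "MeltingDataset", function(x, i) x@curves[[i]])

#' Result of a thermodynamic fit
#'
#' Holds the fitted two-state parameters with their standard deviations,
#' the derived Delta-G 37 and the melting temperature at the reporting
#' concentration (1e-4 M by default), plus fit diagnostics.
#'
#' @slot params a [TwoStateParams-class].
#' @slot dHsd,dSsd standard deviations of dH (kcal/mol) and dS (eu).
#' @slot dG37 an [EnergyWithSD-class].
#' @slot tm melting temperature at `ctRef`, degrees C.
#' @slot ctRef reporting concentration, M.
#' @slot method one of `"curve_fit"`, `"curve_average"`, `"tm_plot"`.
#' @slot diagnostics list (residual norm, convergence, two-state flag, ...).
#' @export
setClass("FitResult",
  representation(params = "TwoStateParams", dHsd = "numeric", dSsd = "numeric",
                 dG37 = "EnergyWithSD", tm = "numeric", ctRef = "numeric",
                 method = "character", diagnostics = "list"),
  validity = function(object) {
    dg <- object@params@dH - T37 * object@params@dS / 1000
    if (abs(dg - object@dG37@value) > 1e-6)
      return("dG37 must equal dH - 310.15 * dS (kcal/mol)")
    if (!object@method %in% c("curve_fit", "curve_average", "tm_plot"))
      return("unknown method")
    TRUE
  })

setMethod("show", "FitResult", function(object) {
  cat(sprintf(
    "FitResult (%s): dH = %.1f +/- %.1f kcal/mol, dS = %.1f +/- %.1f eu\n  dG37 = %.2f +/- %.2f kcal/mol, Tm(%.0e M) = %.1f C\n",
    object@method, object@params@dH, object@dHsd, object@params@dS, object@dSsd,
    object@dG37@value, object@dG37@sd, object@ctRef, object@tm))
})

#' Free-energy increment between two duplexes
#'
#' A Delta-Delta-G 37 (kcal/mol) between two duplexes differing by one
#' terminal addition or one internal substitution, with root-sum-square
#' propagated standard deviation and a context label.
#'
#' @slot delta an [EnergyWithSD-class].
#' @slot context text label, e.g. `"5'PC/3'AG terminal"`.
#' @slot source `"measured"` or `"predicted"`.
#' @export
setClass("IncrementRecord",
  representation(delta = "EnergyWithSD", context = "character",
                 source = "character"),
  validity = function(object) {
    if (!object@source %in% c("measured", "predicted"))
      return("source must be 'measured' or 'predicted'")
    TRUE
  })

setMethod("show", "IncrementRecord", function(object) {
  cat(sprintf("Increment [%s, %s]: %.2f +/- %.2f kcal/mol\n",
              object@context, object@source, object@delta@value, object@delta@sd))
})
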