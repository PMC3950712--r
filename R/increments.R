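## Free-energy increment arithmetic with root-sum-square error propagation.

#' Root-sum-square propagation of standard deviations
#'
#' The standard deviation of a difference (or sum) of two independent
#' quantities: `sqrt(sd_a^2 + sd_b^2)`. Rounding happens only at
#' reporting time.
#'
#' @param sd_a,sd_b non-negative standard deviations.
#' @return The propagated standard deviation.
#' @examples
#' propagateSD(0.47, 0.14)  # 0.49 at 2 decimals
#' @export
propagateSD <- function(sd_a, sd_b) {
  if (any(sd_a < 0) || any(sd_b < 0)) stop("standard deviations must be >= 0")
  sqrt(sd_a^2 + sd_b^2)
}

## does `ext` equal `core` plus exactly one terminal unit? returns the
## context label, or NULL
terminalAdditionLabel <- function(core, ext) {
  tC <- core@top; bC <- core@bottom; tE <- ext@top; bE <- ext@bottom
  dT <- length(tE) - length(tC); dB <- length(bE) - length(bC)
  if (dT < 0 || dB < 0 || dT + dB < 1L || dT > 1L || dB > 1L) return(NULL)
  for (side in c("left", "right")) {
    tAdd <- NULL; bAdd <- NULL
    okT <- if (dT == 0L) identical(tE, tC)
           else if (side == "left") identical(tE[-1L], tC) else identical(tE[-length(tE)], tC)
    okB <- if (dB == 0L) identical(bE, bC)
           else if (side == "left") identical(bE[-1L], bC) else identical(bE[-length(bE)], bC)
    if (!okT || !okB) next
    if (dT == 1L) tAdd <- if (side == "left") tE[1L] else tE[length(tE)]
    if (dB == 1L) bAdd <- if (side == "left") bE[1L] else bE[length(bE)]
    ## left end: top gains at its 5' end, bottom at its 3' end
    lab <- if (side == "left") {
      if (!is.null(tAdd) && !is.null(bAdd)) paste0("5'", tAdd, "/3'", bAdd)
      else if (!is.null(tAdd)) paste0("5'", tAdd) else paste0("3'", bAdd)
    } else {
      if (!is.null(tAdd) && !is.null(bAdd)) paste0("3'", tAdd, "/5'", bAdd)
      else if (!is.null(tAdd)) paste0("3'", tAdd) else paste0("5'", bAdd)
    }
    return(lab)
  }
  NULL
}

#' Measured increment for adding a terminal nucleotide or pair
#'
#' The change in formation free energy between a core duplex and the same
#' duplex extended by exactly one terminal base pair or one dangling
#' nucleotide: `delta = dG(extended) - dG(core)`, with root-sum-square
#' standard deviation. The context label (e.g. `"5'P"`, `"3'P/5'G"`) is
#' derived from the added terminus.
#'
#' @param core,extended [Duplex-class] objects differing by one terminal
#'   unit (checked; the extension may be on either end and either strand).
#' @param dG_core,dG_ext [EnergyWithSD-class] measured formation free
#'   energies of the two duplexes.
#' @return An [IncrementRecord-class] with `source = "measured"`.
#' @examples
#' core <- parseDuplex("CAGUCAGU\nGUCAGUCA")
#' ext  <- parseDuplex("PCAGUCAGU\n GUCAGUCA")
#' terminalIncrement(core, ext, energyWithSD(-10.26, 0.15),
#'                   energyWithSD(-10.92, 0.06))
#' @export
terminalIncrement <- function(core, extended, dG_core, dG_ext) {
  lab <- terminalAdditionLabel(core, extended)
  if (is.null(lab)) {
    ## the same physical extension may be written in the rotated frame
    lab <- terminalAdditionLabel(core, reverseDuplex(extended))
    if (is.null(lab))
      stop("duplexes do not differ by exactly one terminal nucleotide or pair")
  }
  new("IncrementRecord",
      delta = energyWithSD(dG_ext@value - dG_core@value,
                           propagateSD(dG_core@sd, dG_ext@sd)),
      context = paste(lab, "terminal"), source = "measured")
}

#' Measured increment for an internal substitution (e.g. U to Psi)
#'
#' `delta = dG(modified) - dG(reference)`, sd by root-sum-square. Both
#' energies should come from the same analysis route (conventionally the
#' inverse-Tm versus ln(CT/4) plots).
#'
#' @param dG_ref,dG_mod [EnergyWithSD-class] formation free energies of
#'   the reference (U) and modified (Psi) duplexes.
#' @param context optional text label for the substitution site.
#' @return An [IncrementRecord-class] with `source = "measured"`.
#' @examples
#' substitutionIncrement(energyWithSD(-12.01, 0.14), energyWithSD(-14.44, 0.47))
#' @export
substitutionIncrement <- function(dG_ref, dG_mod, context = "substitution") {
  new("IncrementRecord",
      delta = energyWithSD(dG_mod@value - dG_ref@value,
                           propagateSD(dG_ref@sd, dG_mod@sd)),
      context = context, source = "measured")
}
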