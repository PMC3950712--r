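## Two-state bimolecular melting model for non-self-complementary duplexes:
## A + B <-> AB with both strands at CT/2, so K = 2*alpha/((1-alpha)^2 * CT)
## and K(Tm) = 4/CT (alpha = 1/2).

#' Free energy of duplex formation at a temperature
#'
#' `dG(T) = dH - T * dS` with dH in kcal/mol and dS in eu (converted to
#' kcal); at T = 310.15 K this is dG37.
#'
#' @param p a [TwoStateParams-class].
#' @param tempK temperature in Kelvin (> 0); vectorized.
#' @return Free energy in kcal/mol.
#' @export
gibbsAt <- function(p, tempK) {
  if (any(tempK <= 0)) stop("temperature must be positive (Kelvin)")
  p@dH - tempK * p@dS / 1000
}

#' Equilibrium fraction of strands paired
#'
#' Solves the bimolecular mass balance `K(T) = 2*alpha/((1-alpha)^2 * CT)`
#' with `K(T) = exp(-dG(T)/(R*T))` for the unique root in (0, 1), using
#' the cancellation-free closed form `alpha = b / (b + 1 + sqrt(2b + 1))`
#' with `b = K * CT` (evaluated in log space when the duplex is very
#' stable). For a self-complementary duplex (`molecularity = 1`) the
#' factor CT replaces CT/... i.e. `K = 2*alpha/((1-alpha)^2 * CT)` becomes
#' `K = alpha/(2*(1-alpha)^2*CT)`; only the non-self-complementary case is
#' exercised by the shipped reference data.
#'
#' @param p a [TwoStateParams-class].
#' @param ct total single-strand concentration, M (> 0).
#' @param tempK temperature in Kelvin; vectorized.
#' @param molecularity 2 (default, non-self-complementary) or 1.
#' @return alpha in `[0, 1]`, strictly decreasing in temperature.
#' @export
fractionPaired <- function(p, ct, tempK, molecularity = 2) {
  if (ct <= 0) stop("ct must be > 0")
  lnK <- -gibbsAt(p, tempK) / (RGAS * tempK)
  ## b = K * CT (molecularity 2) or 4 * K * CT (self-complementary, so the
  ## same closed form applies to K' = 4K)
  lnb <- lnK + log(ct) + if (molecularity == 1) log(4) else 0
  alpha <- numeric(length(lnb))
  big <- lnb > 40
  ## alpha -> 1 - sqrt(2/b) when b is huge
  alpha[big] <- 1 - sqrt(2) * exp(-lnb[big] / 2)
  b <- exp(lnb[!big])
  alpha[!big] <- b / (b + 1 + sqrt(2 * b + 1))
  pmin(pmax(alpha, 0), 1)
}

#' Concentration-dependent melting temperature
#'
#' From the van't Hoff relation for a bimolecular melt,
#' `1/Tm = (R/dH) * ln(CT/4) + dS/dH`; the returned Tm is the temperature
#' at which half the strands are paired (alpha = 1/2).
#'
#' @param p a [TwoStateParams-class].
#' @param ct total strand concentration, M (default 1e-4, the
#'   conventional reporting concentration).
#' @param celsius return degrees C (default) or Kelvin.
#' @param molecularity 2 (default) or 1 (self-complementary; the log term
#'   becomes `ln(CT)`).
#' @return Melting temperature.
#' @examples
#' meltingTemperature(twoStateParams(-77.6, -217.1), 1e-4)  # 52.7 C
#' @export
meltingTemperature <- function(p, ct = 1e-4, celsius = TRUE, molecularity = 2) {
  if (ct <= 0) stop("ct must be > 0")
  if (p@dH == 0) stop("dH must be nonzero")
  lnTerm <- if (molecularity == 1) log(ct) else log(ct / 4)
  invTm <- (RGAS / p@dH) * lnTerm + (p@dS / 1000) / p@dH
  if (invTm <= 0) stop("nonphysical melting temperature (<= 0 K)")
  tm <- 1 / invTm
  if (celsius) tm - 273.15 else tm
}

#' Construct a melting curve
#'
#' @param temperature strictly increasing grid, degrees C.
#' @param absorbance absorbance values, same length.
#' @param ct total strand concentration, M.
#' @param baselines named numeric(4) `(m_ss, b_ss, m_ds, b_ds)` or `NA`s.
#' @return A [MeltCurve-class].
#' @export
meltCurve <- function(temperature, absorbance, ct,
                      baselines = c(m_ss = NA, b_ss = NA, m_ds = NA, b_ds = NA)) {
  new("MeltCurve", temperature = as.numeric(temperature),
      absorbance = as.numeric(absorbance), ct = as.numeric(ct),
      baselines = as.numeric(baselines))
}

setMethod("show", "MeltCurve", function(object) {
  cat(sprintf("MeltCurve: %d points, %.1f-%.1f C, CT = %.3g M\n",
              length(object@temperature), min(object@temperature),
              max(object@temperature), object@ct))
})

#' Simulate a noiseless absorbance-versus-temperature melting curve
#'
#' The observable is a population-weighted mix of two linear baselines,
#' `A(T) = alpha(T) * (m_ds*T + b_ds) + (1 - alpha(T)) * (m_ss*T + b_ss)`,
#' with baselines linear in degrees C. The single-strand (high-T) baseline
#' sits above the duplex baseline for a hyperchromic melt.
#'
#' @param p a [TwoStateParams-class].
#' @param ct total strand concentration, M.
#' @param baselines named numeric(4) `(m_ss, b_ss, m_ds, b_ds)`.
#' @param grid temperature grid in degrees C (default 0-90 in 1 C steps,
#'   the conventional melt range).
#' @return A [MeltCurve-class] with the generating baselines recorded.
#' @export
simulateCurve <- function(p, ct,
                          baselines = c(m_ss = 8e-4, b_ss = 1.10,
                                        m_ds = 4e-4, b_ds = 0.92),
                          grid = seq(0, 90, by = 1)) {
  stopifnot(length(baselines) == 4L)
  a <- fractionPaired(p, ct, grid + 273.15)
  A <- a * (baselines[3] * grid + baselines[4]) +
       (1 - a) * (baselines[1] * grid + baselines[2])
  meltCurve(grid, A, ct, baselines)
}
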