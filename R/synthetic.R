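## Seeded synthetic melting datasets emulating a nine-concentration UV
## melting experiment (1e-6 to 1e-3 M, 0-90 C, 1 C steps).

#' Generate a synthetic melting dataset
#'
#' One curve per concentration, log-spaced over `ctRange`, each a
#' noiseless two-state curve from [simulateCurve()] plus additive
#' Gaussian absorbance noise. Identical seeds give identical datasets;
#' `noiseSD = 0` gives noiseless curves.
#'
#' Default baselines give roughly 20 percent hyperchromicity (upper
#' single-strand baseline above the duplex baseline), typical of short
#' RNA melts; by construction the recovered thermodynamics do not depend
#' on the baseline choice. The default noise level is 0.2 percent of the
#' curve amplitude.
#'
#' @param p a [TwoStateParams-class], the generating ("true") parameters.
#' @param nConcentrations number of curves (>= 3, default 9).
#' @param ctRange range of total strand concentration, M (log-spaced).
#' @param grid temperature grid, degrees C.
#' @param baselines named numeric(4) `(m_ss, b_ss, m_ds, b_ds)`.
#' @param noiseSD absorbance noise standard deviation; `NULL` (default)
#'   means 0.002 times the baseline separation at mid-grid.
#' @param seed integer seed controlling the noise draws.
#' @return A [MeltingDataset-class].
#' @examples
#' ds <- generateDataset(twoStateParams(-80, -220), seed = 1)
#' length(ds)
#' @export
generateDataset <- function(p, nConcentrations = 9,
                            ctRange = c(1e-6, 1e-3),
                            grid = seq(0, 90, by = 1),
                            baselines = c(m_ss = 8e-4, b_ss = 1.10,
                                          m_ds = 4e-4, b_ds = 0.92),
                            noiseSD = NULL, seed = 1) {
  if (nConcentrations < 3L) stop("need at least 3 concentrations")
  if (is.null(noiseSD)) {
    tmid <- mean(range(grid))
    amp <- abs((baselines[1] * tmid + baselines[2]) -
               (baselines[3] * tmid + baselines[4]))
    noiseSD <- 0.002 * amp
  }
  if (noiseSD < 0) stop("noiseSD must be >= 0")
  cts <- exp(seq(log(ctRange[1]), log(ctRange[2]),
                 length.out = nConcentrations))
  set.seed(seed)
  curves <- lapply(cts, function(ct) {
    cv <- simulateCurve(p, ct, baselines = baselines, grid = grid)
    if (noiseSD > 0)
      cv@absorbance <- cv@absorbance + rnorm(length(grid), 0, noiseSD)
    cv
  })
  new("MeltingDataset", curves = curves)
}
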