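## shared helpers for the test suite

NN <- defaultNNParams()

corePlot <- twoStateParams(-77.6, -217.1)   # core duplex, tm-plot route

## independent oracle: solve the bimolecular mass balance
## K = 2a/((1-a)^2 CT) for a by bisection
bisectAlpha <- function(p, ct, tempK, tol = 1e-13) {
  K <- exp(-(p@dH - tempK * p@dS / 1000) / (1.9872e-3 * tempK))
  f <- function(a) 2 * a / ((1 - a)^2 * ct) - K
  lo <- 0; hi <- 1 - 1e-16
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

## hand-summed NN oracle over the raw shipped table (no canonicalization,
## no engine code): looks keys up in both orientations
rawNNTable <- local({
  path <- system.file("extdata", "nn_parameters.tsv", package = "psithermo")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
})

rawStackLookup <- function(key) {
  ch <- strsplit(key, "")[[1]]
  rot <- paste0(ch[5], ch[4], "/", ch[2], ch[1])
  hit <- rawNNTable$dG37[rawNNTable$type == "stack" &
                         rawNNTable$key %in% c(key, rot)]
  stopifnot(length(hit) == 1L)
  hit
}
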