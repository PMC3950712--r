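## End-to-end orchestration: melting CSVs and/or tabulated measurements in,
## thermodynamics / increments / predicted-vs-measured reports out.

#' Compare measured free energies with nearest-neighbor predictions
#'
#' Per-duplex discrepancy `measured - predicted` (kcal/mol) and a
#' within-tolerance flag. Predictions are computed with [predictDG37()]
#' unless supplied; duplexes whose context is unparameterized get `NA`
#' with the reason recorded (the run is not aborted). The flag allows for
#' experimental error: a row is within tolerance when
#' `|discrepancy| <= tol + sd(measured)`.
#'
#' @param measured data.frame with columns `id`, `dG37`, `dG37_sd`
#'   (signed formation values, kcal/mol).
#' @param params an [NNParameterSet-class].
#' @param duplexes named list of [Duplex-class] objects (names matching
#'   `measured$id`); not needed when `predicted` is given.
#' @param predicted optional numeric vector of predictions (signed,
#'   kcal/mol) aligned with `measured` rows, e.g. published reference
#'   predictions.
#' @param tol tolerance in kcal/mol (default 1).
#' @return A data.frame with columns `id, measured, sd, predicted,
#'   discrepancy, within, note`.
#' @export
comparePredictions <- function(measured, params = defaultNNParams(),
                               duplexes = NULL, predicted = NULL, tol = 1) {
  n <- nrow(measured)
  note <- rep("", n)
  if (is.null(predicted)) {
    predicted <- rep(NA_real_, n)
    for (i in seq_len(n)) {
      d <- duplexes[[measured$id[i]]]
      if (is.null(d)) { note[i] <- "no duplex definition"; next }
      pr <- tryCatch(predictDG37(d, params), error = function(e) e)
      if (inherits(pr, "error")) note[i] <- conditionMessage(pr)
      else predicted[i] <- pr@energy@value
    }
  }
  disc <- measured$dG37 - predicted
  sdv <- if ("dG37_sd" %in% names(measured)) measured$dG37_sd else rep(0, n)
  data.frame(id = measured$id, measured = measured$dG37, sd = sdv,
             predicted = predicted, discrepancy = disc,
             within = abs(disc) <= tol + sdv, note = note,
             stringsAsFactors = FALSE)
}

## measured thermo rows (both routes) for one fitted dataset
thermoRows <- function(id, fit) {
  row <- function(f, method) data.frame(
    id = id, method = method, dH = f@params@dH, dH_sd = f@dHsd,
    dS = f@params@dS, dS_sd = f@dSsd, dG37 = f@dG37@value,
    dG37_sd = f@dG37@sd, tm = f@tm, stringsAsFactors = FALSE)
  out <- rbind(row(fit$curveAverage, "curve_average"),
               row(fit$tmPlot, "tm_plot"))
  out$two_state <- fit$consistency$twoState
  out$rel_dH_diff <- fit$consistency$relDiff
  out
}

## turn the shipped reference compilation into runAnalysis inputs
fixturesAsInputs <- function() {
  fx <- tableFixtures()
  fx$id <- paste(fx$group, fx$variant, sep = ".")
  duplexes <- fx$duplex; names(duplexes) <- fx$id
  measured <- data.frame(id = fx$id, method = "tm_plot",
                         dH = fx$tp_dH, dH_sd = fx$tp_dH_sd,
                         dS = fx$tp_dS, dS_sd = fx$tp_dS_sd,
                         dG37 = fx$tp_dG37, dG37_sd = fx$tp_dG37_sd,
                         tm = fx$tp_tm, stringsAsFactors = FALSE)
  ti <- terminalIncrementFixtures()
  si <- substitutionIncrementFixtures()
  increments <- rbind(
    data.frame(kind = "terminal", ref = paste0(ti$core, ".core"),
               mod = paste(ti$extended_group, ti$extended_variant, sep = "."),
               label = ti$terminus, stringsAsFactors = FALSE),
    data.frame(kind = "substitution", ref = paste0(si$group, ".u"),
               mod = paste0(si$group, ".psi"), label = si$context,
               stringsAsFactors = FALSE))
  list(duplexes = duplexes, measured = measured, increments = increments,
       fixtures = fx)
}

#' Run the full analysis pipeline
#'
#' Ingests duplex definitions plus either melting data (CSV dialect of
#' [readMeltingCSV()]; curves map to duplexes via the
#' `"<duplex_id>:<k>"` id convention) or pre-tabulated measured
#' thermodynamics, then produces
#'
#' 1. a per-duplex thermodynamics table (both analysis routes where
#'    melting data were fitted, with the 15 percent two-state flag),
#' 2. an increments table for the declared core/extended and
#'    reference/modified duplex pairs (measured route: inverse-Tm-plot
#'    values), and
#' 3. a measured-versus-predicted comparison with a discrepancy column;
#'    unparameterized nearest-neighbor contexts are reported per row
#'    without aborting.
#'
#' @param config a list (or path to a YAML file) with elements:
#'   `duplexes` (named list of [Duplex-class], or data.frame with
#'   `id, top, bottom`, or path to such a TSV); `melting` (optional CSV
#'   path or curve list); `measured` (optional data.frame as produced by
#'   fitting, see above); `increments` (optional data.frame with
#'   `kind` ("terminal"/"substitution"), `ref`, `mod`, `label`);
#'   `fixtures = TRUE` to run the shipped reference compilation;
#'   `params` (an [NNParameterSet-class]); `ctRef` (reporting
#'   concentration, default 1e-4 M); `outDir` (optional: write
#'   `thermo.tsv`, `increments.tsv`, `comparison.tsv`).
#' @return A list with `thermo`, `increments`, `comparison` data.frames
#'   and `log` (character vector of per-row notes), invisibly when
#'   `outDir` is set.
#' @export
runAnalysis <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  params <- config$params %||% defaultNNParams()
  ctRef <- config$ctRef %||% 1e-4
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  if (isTRUE(config$fixtures)) {
    fi <- fixturesAsInputs()
    config$duplexes <- fi$duplexes
    config$measured <- fi$measured
    config$increments <- config$increments %||% fi$increments
    say("inputs: shipped reference compilation (%d duplex entries)",
        length(fi$duplexes))
  }

  ## --- duplex definitions -------------------------------------------------
  duplexes <- config$duplexes %||% list()
  if (is.character(duplexes))
    duplexes <- read.delim(duplexes, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (is.data.frame(duplexes)) {
    dl <- lapply(seq_len(nrow(duplexes)),
                 function(i) duplex(duplexes$top[i], duplexes$bottom[i]))
    names(dl) <- duplexes$id
    duplexes <- dl
  }

  ## --- measured thermodynamics -------------------------------------------
  thermo <- config$measured
  if (!is.null(config$melting)) {
    curves <- if (is.character(config$melting)) readMeltingCSV(config$melting)
              else config$melting
    byDuplex <- split(curves, curveDuplexId(names(curves)))
    fitRows <- lapply(names(byDuplex), function(id) {
      ds <- new("MeltingDataset", curves = unname(byDuplex[[id]]))
      fit <- fitMeltingDataset(ds, ctRef = ctRef)
      say("fit %s: %d curves, rel dH diff %.1f%%%s", id, length(ds),
          100 * fit$consistency$relDiff,
          if (fit$consistency$twoState) "" else " [not two-state]")
      thermoRows(id, fit)
    })
    fitted <- do.call(rbind, fitRows)
    thermo <- if (is.null(thermo)) fitted else {
      common <- intersect(names(thermo), names(fitted))
      rbind(thermo[common], fitted[common])
    }
  }
  if (is.null(thermo))
    thermo <- data.frame(id = character(0), method = character(0),
                         dH = numeric(0), dH_sd = numeric(0),
                         dS = numeric(0), dS_sd = numeric(0),
                         dG37 = numeric(0), dG37_sd = numeric(0),
                         tm = numeric(0))

  ## measured dG37 per duplex id, preferring the tm_plot route
  tp <- thermo[thermo$method == "tm_plot", , drop = FALSE]
  energyOf <- function(id) {
    row <- tp[tp$id == id, , drop = FALSE]
    if (nrow(row) < 1L) return(NULL)
    energyWithSD(row$dG37[1], row$dG37_sd[1])
  }

  ## --- increments ---------------------------------------------------------
  inc <- config$increments
  increments <- data.frame(kind = character(0), ref = character(0),
                           mod = character(0), label = character(0),
                           ddG = numeric(0), ddG_sd = numeric(0))
  if (!is.null(inc) && nrow(inc)) {
    rows <- lapply(seq_len(nrow(inc)), function(i) {
      eR <- energyOf(inc$ref[i]); eM <- energyOf(inc$mod[i])
      if (is.null(eR) || is.null(eM)) {
        say("increment %s dropped: missing measured dG37 for %s",
            inc$label[i],
            paste(c(inc$ref[i], inc$mod[i])[c(is.null(eR), is.null(eM))],
                  collapse = ", "))
        return(NULL)
      }
      rec <- if (inc$kind[i] == "terminal")
        terminalIncrement(duplexes[[inc$ref[i]]], duplexes[[inc$mod[i]]],
                          eR, eM)
      else substitutionIncrement(eR, eM, context = inc$label[i])
      data.frame(kind = inc$kind[i], ref = inc$ref[i], mod = inc$mod[i],
                 label = inc$label[i], ddG = rec@delta@value,
                 ddG_sd = rec@delta@sd, stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, TRUE)]
    if (length(rows)) increments <- do.call(rbind, rows)
  }

  ## --- predicted vs measured ----------------------------------------------
  comparison <- if (nrow(tp)) {
    cmp <- comparePredictions(tp, params = params, duplexes = duplexes)
    for (i in which(nzchar(cmp$note)))
      say("prediction %s unavailable: %s", cmp$id[i], cmp$note[i])
    cmp
  } else data.frame(id = character(0), measured = numeric(0), sd = numeric(0),
                    predicted = numeric(0), discrepancy = numeric(0),
                    within = logical(0), note = character(0))

  out <- list(thermo = thermo, increments = increments,
              comparison = comparison, log = log)
  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeThermoTSV(thermo, file.path(config$outDir, "thermo.tsv"))
    fmtInc <- increments
    fmtInc$ddG <- sprintf("%.2f", fmtInc$ddG)
    fmtInc$ddG_sd <- sprintf("%.2f", fmtInc$ddG_sd)
    write.table(fmtInc, file.path(config$outDir, "increments.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    fmtCmp <- comparison
    for (col in c("measured", "sd", "predicted", "discrepancy"))
      fmtCmp[[col]] <- sprintf("%.2f", fmtCmp[[col]])
    write.table(fmtCmp, file.path(config$outDir, "comparison.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(log, file.path(config$outDir, "run.log"))
    return(invisible(out))
  }
  out
}
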