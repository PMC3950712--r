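## Plain-text I/O: melting-data CSV dialect and Table-style thermo TSV.

#' Write melting curves to the melting-data CSV dialect
#'
#' Long format with columns `curve_id, CT_molar, temperature_C,
#' absorbance`; one file may hold many curves (and many duplexes: by
#' convention `curve_id` is `"<duplex_id>:<k>"`).
#'
#' @param ds a [MeltingDataset-class] or list of [MeltCurve-class].
#' @param path output file path.
#' @param ids curve identifiers; default `"<prefix>:1..n"`.
#' @param prefix duplex identifier used to build default ids.
#' @return The path, invisibly.
#' @export
writeMeltingCSV <- function(ds, path, ids = NULL, prefix = "duplex") {
  curves <- if (is(ds, "MeltingDataset")) ds@curves else ds
  if (is.null(ids)) ids <- paste0(prefix, ":", seq_along(curves))
  rows <- do.call(rbind, lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    data.frame(curve_id = ids[i], CT_molar = cv@ct,
               temperature_C = cv@temperature, absorbance = cv@absorbance)
  }))
  write.table(rows, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read melting curves from the melting-data CSV dialect
#'
#' @param path a CSV file with columns `curve_id, CT_molar,
#'   temperature_C, absorbance`.
#' @return A named list of [MeltCurve-class] objects (names = curve ids,
#'   in order of first appearance).
#' @export
readMeltingCSV <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("curve_id", "CT_molar", "temperature_C", "absorbance")
  if (!all(need %in% names(tab)))
    stop("melting CSV must have columns: ", paste(need, collapse = ", "))
  ids <- unique(tab$curve_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$curve_id == id, ]
    sub <- sub[order(sub$temperature_C), ]
    meltCurve(sub$temperature_C, sub$absorbance, sub$CT_molar[1])
  })
  names(out) <- ids
  out
}

## duplex id for a curve id: everything before the last ":"
curveDuplexId <- function(curve_id) sub(":[^:]*$", "", curve_id)

#' Format fitted thermodynamics as a conventional results table
#'
#' One row per duplex and analysis route, printing magnitudes
#' (`neg_dH`, `neg_dS`, `neg_dG37` columns) with the conventional
#' rounding: 1 decimal for dH/dS/Tm, 2 decimals for dG37.
#'
#' @param thermo data.frame with columns `id, method, dH, dH_sd, dS,
#'   dS_sd, dG37, dG37_sd, tm` (signed formation values).
#' @return A data.frame of formatted strings ready for [writeThermoTSV()].
#' @export
formatThermoTable <- function(thermo) {
  pm <- function(v, s, digits) {
    ifelse(is.na(v), "NA",
           ifelse(is.na(s), sprintf(paste0("%.", digits, "f"), v),
                  sprintf(paste0("%.", digits, "f +/- %.", digits, "f"), v, s)))
  }
  data.frame(id = thermo$id, method = thermo$method,
             neg_dH = pm(-thermo$dH, thermo$dH_sd, 1),
             neg_dS = pm(-thermo$dS, thermo$dS_sd, 1),
             neg_dG37 = pm(-thermo$dG37, thermo$dG37_sd, 2),
             tm = sprintf("%.1f", thermo$tm),
             stringsAsFactors = FALSE)
}

#' @describeIn formatThermoTable write the formatted table as TSV.
#' @param path output path.
#' @export
writeThermoTSV <- function(thermo, path) {
  write.table(formatThermoTable(thermo), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
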