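## Loaders for the shipped reference compilation of published duplex
## thermodynamics (pseudouridine pairs, dangling ends, U analogs).

fixturePath <- function(file)
  system.file("extdata", file, package = "psithermo", mustWork = TRUE)

#' Reference duplex thermodynamics compilation
#'
#' Published UV-melting thermodynamics (1 M NaCl, pH 7) for 20
#' pseudouridine-containing test duplexes, their uridine analogs and the
#' two core duplexes they extend: formation dH (kcal/mol), dS (eu), dG37
#' (kcal/mol) with standard deviations and Tm (C at 1e-4 M), for both
#' analysis routes (`cf_` = average of individual curve fits, `tp_` =
#' inverse-Tm versus ln(CT/4) plots). The shipped table stores printed
#' magnitudes; this loader returns signed formation values. `pred_psi` /
#' `pred_wc` carry the published nearest-neighbor duplex predictions
#' where available (signed), and `two_state` is `FALSE` for the one
#' non-two-state melt (two transitions, central U-G).
#'
#' @return A data.frame, one row per table entry (psi / u / core
#'   variants), with a `duplex` list-column of [Duplex-class] objects.
#' @examples
#' fx <- tableFixtures()
#' table(fx$variant)
#' @export
tableFixtures <- function() {
  tab <- read.delim(fixturePath("psi_duplex_thermo.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
  for (col in c("cf_dH", "cf_dS", "cf_dG37", "tp_dH", "tp_dS", "tp_dG37",
                "pred_psi", "pred_wc"))
    tab[[col]] <- -tab[[col]]       # printed magnitudes -> formation sign
  tab$duplex <- lapply(seq_len(nrow(tab)),
                       function(i) duplex(tab$top[i], tab$bottom[i]))
  tab
}

#' @describeIn tableFixtures published terminal-addition increments
#'   (ddG37 for adding a terminal U/P nucleotide or pair to a core
#'   duplex), with propagated sd and published predictions where printed.
#' @export
terminalIncrementFixtures <- function() {
  read.delim(fixturePath("terminal_increments.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

#' @describeIn tableFixtures published internal U-to-P substitution
#'   increments by sequence context.
#' @export
substitutionIncrementFixtures <- function() {
  read.delim(fixturePath("substitution_increments.tsv"), comment.char = "#",
             stringsAsFactors = FALSE)
}

## convenience: one fixture row's tm-plot dG37 as EnergyWithSD
fixtureEnergy <- function(tab, group, variant, method = c("tp", "cf")) {
  method <- match.arg(method)
  row <- tab[tab$group == group & tab$variant == variant, ]
  if (nrow(row) != 1L) stop("no unique fixture row for ", group, "/", variant)
  energyWithSD(row[[paste0(method, "_dG37")]],
               row[[paste0(method, "_dG37_sd")]])
}
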