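# Bundled reference tables for the six bisphenol analogs (BPA, BPS, BPE,
# BPF, BPB, BPAF) binding the progesterone-receptor ligand-binding domain:
# docking scores, MM/GBSA energy decompositions, CD secondary-structure
# fractions, fluorescence-derived quenching/binding constants, and the
# 13-metric ToxPi input. Cells that are not verifiable against a printed
# source (figure-read estimates) are flagged `figure_estimate_synthetic` in
# the companion provenance table.

bp_extdata <- function(file) {
  system.file("extdata", file, package = "bprisk", mustWork = TRUE)
}

#' Bundled docking scores of bisphenol analogs against PR-LBD
#'
#' @return Data frame `chemical`, `score` (kcal/mol-scale; more negative =
#'   stronger binding).
#' @export
bp_docking <- function() {
  utils::read.csv(bp_extdata("docking_scores.csv"), stringsAsFactors = FALSE)
}

#' Bundled MM/GBSA energy decompositions
#'
#' Van der Waals, electrostatic, polar- and nonpolar-solvation components and
#' the total binding free energy (kcal/mol) with standard errors.
#'
#' @return Data frame as read by [read_energy_csv()].
#' @export
bp_energy_decomposition <- function() {
  read_energy_csv(bp_extdata("mmgbsa_components.csv"))
}

#' Bundled CD secondary-structure fractions
#'
#' Percent alpha-helix, beta-sheet, beta-turn and random coil of PR-LBD
#' alone (`control`, molar ratio 0:1) and with each bisphenol analog at
#' 10:1.
#'
#' @return Data frame with columns `sample`, `ratio`, `alpha_helix`,
#'   `beta_sheet`, `beta_turn`, `random_coil`.
#' @export
bp_secondary_structure <- function() {
  utils::read.csv(bp_extdata("secondary_structure.csv"),
                  stringsAsFactors = FALSE)
}

#' Bundled fluorescence quenching and binding constants
#'
#' Stern--Volmer constants (x1e4 L/mol) and association constants
#' (x1e4 L/mol) per system and temperature; cells not measurable for a
#' system (e.g. enhancement-only behaviour) are `NA`.
#'
#' @return Data frame `system`, `T_K`, `ksv_1e4`, `ka_1e4`.
#' @export
bp_binding_constants <- function() {
  utils::read.csv(bp_extdata("binding_constants.csv"),
                  stringsAsFactors = FALSE)
}

#' Binding constants reshaped for the thermodynamics table
#'
#' @return Named list system -> named numeric vector of Ka (L/mol) keyed by
#'   temperature (K), suitable for [thermo_table()].
#' @export
bp_ka_by_T <- function() {
  bc <- bp_binding_constants()
  bc <- bc[!is.na(bc$ka_1e4), ]
  lapply(split(bc, bc$system), function(g) {
    stats::setNames(g$ka_1e4 * 1e4, g$T_K)
  })
}

#' Bundled 13-metric ToxPi input for the six bisphenol analogs
#'
#' Thirteen metrics in five classes (in silico binding, chemical analysis,
#' in vitro binding, cytotoxicity, PR expression) with the transforms and
#' control values of the packaged configuration. Metric slots without a
#' printed source are synthetic figure-read estimates; see the provenance
#' table (`provenance` attribute) and note that only the top-ranked chemical
#' is treated as a verified outcome.
#'
#' @return A [metric_table()]; attribute `"provenance"` holds the long-format
#'   source table for non-printed cells.
#' @export
bp_toxpi_fixture <- function() {
  mt <- read_metric_table(bp_extdata("toxpi_metrics.csv"),
                          bp_extdata("toxpi_config.json"))
  attr(mt, "provenance") <- utils::read.csv(
    bp_extdata("toxpi_metrics_source.csv"), stringsAsFactors = FALSE)
  mt
}
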