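# Two-point van't Hoff thermodynamics of ligand binding:
#   dH = R ln(k2/k1) / (1/T1 - 1/T2)      (exact two-point solution)
#   dG = -R T ln(Ka)
#   dS = (dH - dG) / T
# R = 8.314 J mol^-1 K^-1; all outputs in kJ/mol (dS in kJ mol^-1 K^-1).

GAS_CONSTANT <- 8.314  # J mol^-1 K^-1

#' van't Hoff binding enthalpy from two temperatures
#'
#' Exact two-point solution of the van't Hoff relation
#' `ln(k2/k1) = dH (1/T1 - 1/T2) / R` — no regression, so exactly two
#' binding constants are required.
#'
#' @param k1,k2 Binding constants (L/mol) at `T1` and `T2`.
#' @param T1,T2 Temperatures in K, distinct.
#' @param R Gas constant in J mol^-1 K^-1.
#' @return Enthalpy change in kJ/mol.
#' @export
vant_hoff_enthalpy <- function(k1, T1, k2, T2, R = GAS_CONSTANT) {
  if (k1 <= 0 || k2 <= 0) stop("binding constants must be positive")
  if (T1 == T2) stop("T1 and T2 must differ")
  R * log(k2 / k1) / (1 / T1 - 1 / T2) / 1000
}

#' Gibbs free energy of binding
#'
#' `dG = -R T ln(Ka)`; negative values mean spontaneous association.
#'
#' @param ka Binding constant in L/mol (> 0).
#' @param T Temperature in K (> 0).
#' @param R Gas constant in J mol^-1 K^-1.
#' @return Free-energy change in kJ/mol.
#' @export
gibbs_free_energy <- function(ka, T, R = GAS_CONSTANT) {
  if (any(ka <= 0)) stop("ka must be positive")
  if (any(T <= 0)) stop("T must be positive")
  -R * T * log(ka) / 1000
}

#' Entropy change of binding
#'
#' `dS = (dH - dG) / T`, the Gibbs--Helmholtz rearrangement.
#'
#' @param dH Enthalpy change, kJ/mol.
#' @param dG Free-energy change, kJ/mol.
#' @param T Temperature in K (> 0).
#' @return Entropy change in kJ mol^-1 K^-1.
#' @export
entropy_change <- function(dH, dG, T) {
  if (any(T <= 0)) stop("T must be positive")
  (dH - dG) / T
}

#' Classify the dominant noncovalent binding force
#'
#' Sign-pattern rules for (dH, dS): both positive indicates hydrophobic
#' interaction, both negative van der Waals forces plus hydrogen bonding,
#' negative enthalpy with positive entropy electrostatic interaction
#' (the standard Ross--Subramanian convention). Any component within `tol`
#' of zero — or the thermodynamically unfavourable dH > 0, dS < 0 pattern —
#' is reported as mixed.
#'
#' @param dH Enthalpy change, kJ/mol.
#' @param dS Entropy change, kJ mol^-1 K^-1.
#' @param tol Tolerance around zero.
#' @return One of `"hydrophobic"`, `"vdw_hbond"`, `"electrostatic"`,
#'   `"mixed"`.
#' @export
classify_binding_forces <- function(dH, dS, tol = 1e-6) {
  if (abs(dH) <= tol || abs(dS) <= tol) return("mixed")
  if (dH > 0 && dS > 0) return("hydrophobic")
  if (dH < 0 && dS < 0) return("vdw_hbond")
  if (dH < 0 && dS > 0) return("electrostatic")
  "mixed"
}

#' Thermodynamic parameter table for a set of binding systems
#'
#' For each system, computes dG at every temperature with a binding constant,
#' and — when constants at exactly two temperatures are available — the
#' van't Hoff dH, the entropy change dS (reported at the lower temperature),
#' whether binding is spontaneous at all temperatures, and the dominant-force
#' class. Systems measured at a single temperature get dG only; dH/dS are NA.
#'
#' @param ka_by_T Named list: one element per system, each a named numeric
#'   vector of binding constants (L/mol) keyed by temperature in K, e.g.
#'   `list(BPA = c("298" = 9800, "310" = 36700))`.
#' @param R Gas constant in J mol^-1 K^-1.
#' @return Data frame of class `thermo_table` with one row per system and
#'   temperature: `system`, `T_K`, `ka`, `dG_kJmol`, `dH_kJmol`,
#'   `dS_kJmolK`, `force_class`, `spontaneous`.
#' @export
thermo_table <- function(ka_by_T, R = GAS_CONSTANT) {
  rows <- lapply(names(ka_by_T), function(sys) {
    kas <- ka_by_T[[sys]]
    kas <- kas[!is.na(kas)]
    if (!length(kas)) return(NULL)
    temps <- as.numeric(names(kas))
    ord <- order(temps)
    temps <- temps[ord]; kas <- kas[ord]
    dG <- gibbs_free_energy(unname(kas), temps, R = R)
    two <- length(kas) == 2
    dH <- if (two) {
      vant_hoff_enthalpy(kas[[1]], temps[[1]], kas[[2]], temps[[2]], R = R)
    } else NA_real_
    dS <- if (two) entropy_change(dH, dG[[1]], temps[[1]]) else NA_real_
    fc <- if (two) classify_binding_forces(dH, dS) else NA_character_
    data.frame(system = sys, T_K = temps, ka = unname(kas), dG_kJmol = dG,
               dH_kJmol = dH, dS_kJmolK = dS, force_class = fc,
               spontaneous = all(dG < 0))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(system = character(), T_K = numeric(), ka = numeric(),
                      dG_kJmol = numeric(), dH_kJmol = numeric(),
                      dS_kJmolK = numeric(), force_class = character(),
                      spontaneous = logical())
  }
  rownames(out) <- NULL
  class(out) <- c("thermo_table", class(out))
  out
}

#' Write a binding-constants/thermodynamics summary CSV
#'
#' Emits the conventional per-system layout (system, T, Ksv x1e4, Kq x1e12,
#' Ka x1e4, dH, dG, dS) with absent cells as empty strings.
#'
#' @param tab A [thermo_table()] result.
#' @param quench Optional data frame with `system`, `T_K`, `ksv` (L/mol) and
#'   `tau0` columns supplying the quenching constants for matching rows.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thermo_csv <- function(tab, path, quench = NULL) {
  fmt <- function(x, d = 3) ifelse(is.na(x), "", formatC(x, digits = d, format = "f"))
  ksv <- kq <- rep(NA_real_, nrow(tab))
  if (!is.null(quench)) {
    idx <- match(paste(tab$system, tab$T_K), paste(quench$system, quench$T_K))
    ksv <- quench$ksv[idx]
    tau0 <- if ("tau0" %in% names(quench)) quench$tau0[idx] else 1e-8
    kq <- ksv / tau0
  }
  # dH/dS printed once per system (on the lower-temperature row)
  first <- !duplicated(tab$system)
  out <- data.frame(
    system = tab$system, T_K = tab$T_K,
    Ksv_1e4 = fmt(ksv / 1e4, 2), Kq_1e12 = fmt(kq / 1e12, 2),
    Ka_1e4 = fmt(tab$ka / 1e4, 2),
    dH_kJmol = ifelse(first, fmt(tab$dH_kJmol), ""),
    dG_kJmol = fmt(tab$dG_kJmol),
    dS_kJmolK = ifelse(first, fmt(tab$dS_kJmolK), ""),
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
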