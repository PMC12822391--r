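# Validation and summarization of docking, MM/GBSA energy-decomposition and
# CD secondary-structure tables; the DEG-intersection biomarker screen; and
# small assay-derived quantities (tumor volume, fold changes). Energies stay
# in kcal/mol here (the docking/MM/GBSA convention); the thermodynamics
# module works in kJ/mol and the two are never mixed.

#' Validate additivity of an MM/GBSA energy decomposition
#'
#' The total binding free energy must equal the sum of its van der Waals,
#' electrostatic, polar-solvation and nonpolar-solvation components.
#'
#' @param rec Named list or one-row data frame with `e_vdw`, `e_ele`,
#'   `g_sol_polar`, `g_sol_nonpolar`, `g_binding` (kcal/mol).
#' @param tol Allowed absolute discrepancy (kcal/mol).
#' @return List: `ok` (logical) and `delta` (signed sum-minus-total).
#' @export
validate_energy_decomposition <- function(rec, tol = 0.01) {
  comp <- c("e_vdw", "e_ele", "g_sol_polar", "g_sol_nonpolar")
  vals <- vapply(c(comp, "g_binding"), function(f) as.numeric(rec[[f]]),
                 numeric(1))
  if (any(!is.finite(vals))) stop("all energy components must be finite")
  delta <- sum(vals[comp]) - vals[["g_binding"]]
  # small slack over tol so a component sum printed at exactly the tolerance
  # is not rejected by floating-point representation error
  list(ok = abs(delta) <= tol + 1e-9, delta = delta)
}

#' Rank chemicals by a scalar value
#'
#' Stable ranking with rank 1 = best. With `ascending = TRUE` the most
#' negative value wins (the convention for docking scores and binding free
#' energies); ties are broken lexicographically by chemical name.
#'
#' @param records Data frame with columns `chemical` and `value`.
#' @param ascending If `TRUE`, smaller (more negative) values rank first.
#' @return Data frame `chemical`, `value`, `rank`, ordered by rank.
#' @export
rank_chemicals_by_value <- function(records, ascending = TRUE) {
  stopifnot(all(c("chemical", "value") %in% names(records)))
  if (anyDuplicated(records$chemical)) stop("duplicate chemical names")
  if (any(!is.finite(records$value))) stop("values must be finite")
  v <- if (ascending) records$value else -records$value
  ord <- order(v, records$chemical)
  out <- records[ord, c("chemical", "value")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Validate that CD secondary-structure fractions sum to 100%
#'
#' @param ss Named list or one-row data frame with `alpha_helix`,
#'   `beta_sheet`, `beta_turn`, `random_coil` in percent.
#' @param tol Allowed deviation of the sum from 100.
#' @return List: `ok` (logical) and `sum` (the actual sum).
#' @export
validate_secondary_structure <- function(ss, tol = 0.5) {
  elems <- c("alpha_helix", "beta_sheet", "beta_turn", "random_coil")
  vals <- vapply(elems, function(f) as.numeric(ss[[f]]), numeric(1))
  if (any(vals < 0)) stop("secondary-structure fractions must be >= 0")
  s <- sum(vals)
  list(ok = abs(s - 100) <= tol, sum = s)
}

#' Secondary-structure change versus control
#'
#' Per-element treated-minus-control difference and its absolute value, in
#' percentage points.
#'
#' @param treated,control Rows as accepted by
#'   [validate_secondary_structure()].
#' @return Data frame `element`, `delta`, `abs_delta`.
#' @export
secondary_structure_delta <- function(treated, control) {
  elems <- c("alpha_helix", "beta_sheet", "beta_turn", "random_coil")
  d <- vapply(elems, function(f) {
    as.numeric(treated[[f]]) - as.numeric(control[[f]])
  }, numeric(1))
  data.frame(element = elems, delta = unname(d), abs_delta = abs(unname(d)),
             row.names = NULL)
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `|log2fc| > fc_thresh` and `p < p_thresh`, both strict.
#' Records with a malformed p-value (<= 0 or > 1) are dropped with a warning
#' reporting how many.
#'
#' @param records Data frame with columns `gene`, `log2fc`, `p`.
#' @param fc_thresh Absolute log2 fold-change threshold (strict).
#' @param p_thresh P-value threshold (strict).
#' @return Character vector of gene symbols passing both criteria.
#' @export
filter_degs <- function(records, fc_thresh = 1, p_thresh = 0.05) {
  stopifnot(all(c("gene", "log2fc", "p") %in% names(records)))
  bad <- !is.finite(records$p) | records$p <= 0 | records$p > 1
  if (any(bad)) {
    warning(sprintf("dropped %d record(s) with malformed p-values", sum(bad)))
    records <- records[!bad, ]
  }
  keep <- abs(records$log2fc) > fc_thresh & records$p < p_thresh
  unique(records$gene[keep])
}

#' Intersect gene sets
#'
#' Symbols present in every input set; case-sensitive exact matching, no
#' alias resolution.
#'
#' @param sets List of at least two character vectors.
#' @return Character vector (sorted) of common symbols.
#' @export
intersect_gene_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 gene sets to intersect")
  sort(Reduce(intersect, lapply(sets, unique)))
}

#' Caliper tumor volume
#'
#' `V = L * W^2 / 2` in mm^3. Width exceeding length triggers a warning
#' (probable caliper-axis swap) but the volume is computed as given.
#'
#' @param length_mm,width_mm Caliper measurements in mm; width must be > 0.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(width_mm <= 0) || any(length_mm <= 0)) {
    stop("length and width must be positive")
  }
  if (any(width_mm > length_mm)) {
    warning("width exceeds length; computing with the values as given")
  }
  length_mm * width_mm^2 / 2
}

#' Fold change versus control
#'
#' @param treated Treated-group value.
#' @param control Control-group value (> 0).
#' @return `treated / control`.
#' @export
fold_change_vs_control <- function(treated, control) {
  if (any(control <= 0)) stop("control value must be positive")
  treated / control
}

#' Run the DEG-intersection biomarker screen
#'
#' Applies the strict fold-change/significance filter to each condition's DEG
#' table, then intersects the per-condition pass sets with the disease gene
#' list. Genes surviving every set are the consensus biomarker candidates.
#'
#' @param deg_tables Named list of DEG data frames (`gene`, `log2fc`, `p`),
#'   one per exposure condition.
#' @param disease_genes Character vector of disease-associated gene symbols.
#' @param fc_thresh,p_thresh Passed to [filter_degs()].
#' @return List: `candidates` (character), `per_condition` (named list of
#'   filtered gene sets), `n_disease_genes`.
#' @export
biomarker_screen <- function(deg_tables, disease_genes, fc_thresh = 1,
                             p_thresh = 0.05) {
  if (!length(deg_tables)) stop("no DEG tables supplied")
  per <- lapply(deg_tables, filter_degs, fc_thresh = fc_thresh,
                p_thresh = p_thresh)
  cands <- intersect_gene_sets(c(per, list(unique(disease_genes))))
  list(candidates = cands, per_condition = per,
       n_disease_genes = length(unique(disease_genes)))
}

# ---- CSV readers for the table shapes this module consumes ----------------

#' Read an MM/GBSA component table
#'
#' Columns: `chemical, e_vdw, e_ele, g_sol_polar, g_sol_nonpolar, g_binding`
#' (kcal/mol), optionally matching `*_sem` columns.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_energy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chemical", "e_vdw", "e_ele", "g_sol_polar", "g_sol_nonpolar",
            "g_binding")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  df
}

#' Read a 3-column DEG table (gene, log2fc, pvalue)
#'
#' @param path CSV path.
#' @return Data frame with columns `gene`, `log2fc`, `p`.
#' @export
read_deg_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  nm <- names(df)
  if ("pvalue" %in% nm && !"p" %in% nm) names(df)[nm == "pvalue"] <- "p"
  need <- c("gene", "log2fc", "p")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  df[, need]
}

#' Read a one-symbol-per-line gene list
#'
#' @param path Text file path.
#' @return Character vector of symbols (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
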