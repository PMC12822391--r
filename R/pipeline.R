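# Pipeline assembly: a run configuration carrying every constant and
# threshold, and a driver that executes whichever stages have inputs,
# writes per-stage CSVs plus a combined JSON report, and collects stage
# failures without aborting independent stages.

#' Pipeline run configuration
#'
#' Bundles the physical constants and decision thresholds used across the
#' stages; the configuration is echoed verbatim into every report.
#'
#' @param tau0 Unquenched fluorescence lifetime, s.
#' @param R Gas constant, J mol^-1 K^-1.
#' @param kq_limit Diffusion-limited collisional quenching ceiling,
#'   L mol^-1 s^-1.
#' @param ka_range Biologically relevant association-constant range, L/mol.
#' @param fc_thresh,p_thresh DEG filter thresholds.
#' @param shift_nm Spectral-shift significance threshold, nm.
#' @param ss_tol Secondary-structure sum tolerance, percent.
#' @param energy_tol MM/GBSA additivity tolerance, kcal/mol.
#' @param toxpi_weights Named class weights (`NULL` = uniform).
#' @param seed Integer seed consumed by any stochastic stage.
#' @return Object of class `run_config`.
#' @export
run_config <- function(tau0 = 1e-8, R = 8.314, kq_limit = 2e10,
                       ka_range = c(1e4, 1e6), fc_thresh = 1,
                       p_thresh = 0.05, shift_nm = 2, ss_tol = 0.5,
                       energy_tol = 0.01, toxpi_weights = NULL, seed = 1L) {
  stopifnot(tau0 > 0, R > 0, kq_limit > 0, all(ka_range > 0))
  structure(list(tau0 = tau0, R = R, kq_limit = kq_limit,
                 ka_range = ka_range, fc_thresh = fc_thresh,
                 p_thresh = p_thresh, shift_nm = shift_nm, ss_tol = ss_tol,
                 energy_tol = energy_tol, toxpi_weights = toxpi_weights,
                 seed = as.integer(seed)),
            class = "run_config")
}

run_stage <- function(report, name, expr) {
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           error = conditionMessage(e)))
  report$stages[[name]] <- res
  if (!res$ok) {
    report$failures <- c(report$failures, name)
    message(sprintf("stage '%s' failed: %s", name, res$error))
  }
  report
}

#' Run the integrated analysis pipeline
#'
#' Executes, for whichever inputs are present: the DEG biomarker screen,
#' fluorescence titration analysis (peak location, trend, Stern--Volmer and
#' binding fits), van't Hoff thermodynamics, CETSA melt-curve fitting,
#' docking/MM/GBSA/secondary-structure table validation and ranking, and
#' ToxPi risk integration. Per-stage CSVs and a combined JSON report are
#' written under `out_dir`; stage failures are collected and reported, and
#' independent stages still run.
#'
#' @param config A [run_config()].
#' @param inputs Named list of file paths; recognized names: `titration`,
#'   `cetsa`, `deg_tables` (character vector), `disease_genes`, `docking`,
#'   `energy`, `secondary_structure`, `toxpi_values`, `toxpi_config`.
#'   Unrecognized names are ignored.
#' @param out_dir Output directory (created).
#' @param cetsa_control Control sample name in the CETSA table.
#' @return Invisibly, the report list; element `failures` names failed
#'   stages (empty character if all ran clean).
#' @export
run_pipeline <- function(config, inputs, out_dir,
                         cetsa_control = "Veh") {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = unclass(config), stages = list(),
                 failures = character())

  if (!is.null(inputs$deg_tables)) {
    report <- run_stage(report, "screen", {
      tabs <- lapply(inputs$deg_tables, read_deg_csv)
      names(tabs) <- basename(unlist(inputs$deg_tables))
      disease <- read_gene_list(inputs$disease_genes)
      scr <- biomarker_screen(tabs, disease, config$fc_thresh,
                              config$p_thresh)
      writeLines(scr$candidates, file.path(out_dir, "biomarker_candidates.txt"))
      scr[c("candidates", "n_disease_genes")]
    })
  }

  if (!is.null(inputs$titration)) {
    report <- run_stage(report, "fluorescence", {
      series_list <- read_titration_csv(inputs$titration)
      rows <- lapply(names(series_list), function(key) {
        ts <- series_list[[key]]
        ctrl <- ts$spectra[[1]]  # sorted by conc: first is the F0 scan
        lam <- characterize_spectrum(ctrl)$lambda_max
        ser <- extract_intensity_series(ts, lambda_ref = lam)
        trend <- monotonic_trend(ser)
        row <- data.frame(series = key, protein = ts$protein,
                          ligand = ts$ligand, T_K = ts$temperature,
                          lambda_max = lam, trend = trend,
                          ksv = NA_real_, kq = NA_real_, r2_sv = NA_real_,
                          ka = NA_real_, n_sites = NA_real_,
                          model = NA_character_, ka_optimal = NA)
        if (trend == "decreasing") {
          # tol = 0.05 keeps measurement noise from misflagging a mildly
          # quenched low-concentration point as enhancement
          qf <- stern_volmer_fit(ser, ts$temperature, tau0 = config$tau0,
                                 tol = 0.05)
          bf <- double_log_fit(ser, ts$temperature)
          row$ksv <- qf$ksv; row$kq <- qf$kq; row$r2_sv <- qf$r2
          row$ka <- bf$ka; row$n_sites <- bf$n_sites; row$model <- bf$model
        } else if (trend == "increasing") {
          bf <- enhancement_fit(ser, ts$temperature)
          row$ka <- bf$ka; row$model <- bf$model
        }
        if (!is.na(row$ka)) {
          row$ka_optimal <- ka_in_optimal_range(row$ka, config$ka_range[1],
                                                config$ka_range[2])
        }
        row
      })
      fl <- do.call(rbind, rows)
      utils::write.csv(format_sig(fl), file.path(out_dir, "fluorescence.csv"),
                       row.names = FALSE)
      fl
    })
  }

  fl <- report$stages$fluorescence
  if (!is.null(fl) && fl$ok && any(!is.na(fl$value$ka))) {
    report <- run_stage(report, "thermodynamics", {
      fv <- fl$value[!is.na(fl$value$ka), ]
      key <- paste(fv$protein, fv$ligand, sep = ":")
      ka_by_T <- lapply(split(fv, key), function(g) {
        stats::setNames(g$ka, g$T_K)
      })
      tt <- thermo_table(ka_by_T, R = config$R)
      utils::write.csv(format_sig(tt), file.path(out_dir, "thermodynamics.csv"),
                       row.names = FALSE)
      tt
    })
  }

  if (!is.null(inputs$cetsa)) {
    report <- run_stage(report, "cetsa", {
      ct <- cetsa_analysis(inputs$cetsa, control = cetsa_control)
      utils::write.csv(format_sig(ct), file.path(out_dir, "cetsa.csv"),
                       row.names = FALSE)
      ct
    })
  }

  if (!is.null(inputs$docking)) {
    report <- run_stage(report, "docking", {
      dk <- utils::read.csv(inputs$docking, stringsAsFactors = FALSE)
      rk <- rank_chemicals_by_value(
        data.frame(chemical = dk$chemical, value = dk$score),
        ascending = TRUE)
      utils::write.csv(rk, file.path(out_dir, "docking_ranked.csv"),
                       row.names = FALSE)
      rk
    })
  }

  if (!is.null(inputs$energy)) {
    report <- run_stage(report, "energy", {
      en <- read_energy_csv(inputs$energy)
      checks <- lapply(seq_len(nrow(en)), function(i) {
        validate_energy_decomposition(en[i, ], tol = config$energy_tol)
      })
      en$additivity_ok <- vapply(checks, `[[`, logical(1), "ok")
      en$additivity_delta <- vapply(checks, `[[`, numeric(1), "delta")
      if (!all(en$additivity_ok)) {
        stop("MM/GBSA additivity violated for: ",
             paste(en$chemical[!en$additivity_ok], collapse = ", "))
      }
      rk <- rank_chemicals_by_value(
        data.frame(chemical = en$chemical, value = en$g_binding),
        ascending = TRUE)
      utils::write.csv(rk, file.path(out_dir, "energy_ranked.csv"),
                       row.names = FALSE)
      list(table = en, ranking = rk)
    })
  }

  if (!is.null(inputs$secondary_structure)) {
    report <- run_stage(report, "secondary_structure", {
      ss <- utils::read.csv(inputs$secondary_structure,
                            stringsAsFactors = FALSE)
      ok <- vapply(seq_len(nrow(ss)), function(i) {
        validate_secondary_structure(ss[i, ], tol = config$ss_tol)$ok
      }, logical(1))
      if (!all(ok)) {
        stop("secondary-structure fractions do not sum to 100 for: ",
             paste(ss$sample[!ok], collapse = ", "))
      }
      ctrl <- ss[ss$sample == "control", ]
      if (nrow(ctrl) != 1) stop("need exactly one 'control' row")
      deltas <- do.call(rbind, lapply(which(ss$sample != "control"),
        function(i) {
          d <- secondary_structure_delta(ss[i, ], ctrl)
          cbind(sample = ss$sample[[i]], d)
        }))
      utils::write.csv(format_sig(deltas),
                       file.path(out_dir, "secondary_structure_deltas.csv"),
                       row.names = FALSE)
      deltas
    })
  }

  if (!is.null(inputs$toxpi_values)) {
    report <- run_stage(report, "toxpi", {
      mt <- read_metric_table(inputs$toxpi_values, inputs$toxpi_config)
      res <- toxpi_scores(mt, weights = config$toxpi_weights)
      utils::write.csv(format_sig(as.data.frame(res)),
                       file.path(out_dir, "toxpi_scores.csv"),
                       row.names = FALSE)
      as.data.frame(res)
    })
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(report)
}

# round numeric columns to 6 significant digits for CSV emission
format_sig <- function(df, digits = 6) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}
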