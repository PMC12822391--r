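# Seeded synthetic-data generators producing pipeline inputs with known
# ground truth: titration spectra under the static-quenching and enhancement
# forward models, sigmoidal CETSA melt curves with planted Tm50 shifts, DEG
# tables with a planted consensus overlap, and ToxPi metric tables with an
# optional dominant chemical. Every generator is deterministic given
# cfg$seed (RNG state is scoped, not leaked).

#' Simulation configuration
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @param noise_sd Multiplicative Gaussian noise level as a fraction of
#'   signal (>= 0; 0 disables noise).
#' @param n_points Number of quencher concentrations when none are given
#'   explicitly (>= 2).
#' @param temperature_K Temperature attached to generated spectra.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, noise_sd = 0, n_points = 6L,
                       temperature_K = 298) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_points < 2) stop("n_points must be >= 2")
  structure(list(seed = as.integer(seed), noise_sd = noise_sd,
                 n_points = as.integer(n_points),
                 temperature_K = temperature_K),
            class = "sim_config")
}

# Default titration concentrations: 0, 1, 5, 10, 15, 20 uM (the standard
# bisphenol titration ladder).
default_concs <- function(n = 6L) {
  full <- c(0, 1, 5, 10, 15, 20) / 1e6
  if (n <= 6) full[seq_len(n)] else c(full, seq(25, by = 5,
                                                length.out = n - 6) / 1e6)
}

# multiplicative Gaussian noise truncated at 0 (fluorescence noise scales
# with signal)
apply_noise <- function(x, noise_sd) {
  if (noise_sd == 0) return(x)
  pmax(0, x * (1 + stats::rnorm(length(x), sd = noise_sd)))
}

# Gaussian emission band over the 300-400 nm window
gaussian_band <- function(wavelengths, peak, lambda_max, width) {
  peak * exp(-(wavelengths - lambda_max)^2 / (2 * width^2))
}

#' Generate a static-quenching titration series
#'
#' Forward model: the peak intensity at concentration Q is
#' `f0 / (1 + ksv_true * Q)` (complex-forming quenching); each spectrum is a
#' Gaussian emission band centred at `lambda_max` over 300--400 nm, with
#' multiplicative Gaussian noise of sd `cfg$noise_sd` applied per point.
#'
#' @param ksv_true True Stern--Volmer constant, L/mol.
#' @param f0 Unquenched peak intensity, a.u. (> 0).
#' @param lambda_max Emission-peak wavelength, nm.
#' @param concs Quencher concentrations in mol/L, must include 0 and be
#'   non-negative; defaults to the 0--20 uM ladder with `cfg$n_points`
#'   levels.
#' @param cfg A [sim_config()].
#' @param width Gaussian band width (sd) in nm.
#' @param wavelengths Sampled emission wavelengths.
#' @return A [titration_series()] with attribute `"truth"` recording the
#'   generating parameters.
#' @export
gen_titration_series <- function(ksv_true, f0, lambda_max = 335,
                                 concs = NULL, cfg = sim_config(),
                                 width = 25, wavelengths = 300:400) {
  if (is.null(concs)) concs <- default_concs(cfg$n_points)
  if (!length(concs)) stop("concs must be non-empty")
  if (any(concs < 0)) stop("concentrations must be non-negative")
  if (!any(concs == 0)) stop("concs must include 0 (the F0 scan)")
  if (f0 <= 0) stop("f0 must be positive")
  withr::with_seed(cfg$seed, {
    spectra <- lapply(concs, function(q) {
      peak <- f0 / (1 + ksv_true * q)
      ints <- apply_noise(gaussian_band(wavelengths, peak, lambda_max, width),
                          cfg$noise_sd)
      emission_spectrum(wavelengths, ints, q, cfg$temperature_K)
    })
    ts <- titration_series("protein", "ligand", spectra)
  })
  attr(ts, "truth") <- list(model = "static_quench", ksv = ksv_true, f0 = f0,
                            lambda_max = lambda_max)
  ts
}

#' Generate a fluorescence-enhancement titration series
#'
#' Forward model (algebraic inversion of the saturation relation
#' `(Finf - F0)/(Fx - F0) = 1 + 1/(Ka Q)`): the peak intensity at Q is
#' `f0 + (f_inf - f0) * ka_true * Q / (1 + ka_true * Q)`, rising from f0
#' toward the saturation plateau f_inf.
#'
#' @param ka_true True association constant, L/mol (> 0).
#' @param f0 Zero-quencher peak intensity (> 0).
#' @param f_inf Saturation peak intensity (> f0).
#' @inheritParams gen_titration_series
#' @return A [titration_series()] with a `"truth"` attribute.
#' @export
gen_enhancement_series <- function(ka_true, f0, f_inf, lambda_max = 335,
                                   concs = NULL, cfg = sim_config(),
                                   width = 25, wavelengths = 300:400) {
  if (f_inf <= f0) stop("f_inf must exceed f0 for an enhancement series")
  if (ka_true <= 0) stop("ka_true must be positive")
  if (is.null(concs)) concs <- default_concs(cfg$n_points)
  if (any(concs < 0)) stop("concentrations must be non-negative")
  if (!any(concs == 0)) stop("concs must include 0 (the F0 scan)")
  withr::with_seed(cfg$seed, {
    spectra <- lapply(concs, function(q) {
      peak <- f0 + (f_inf - f0) * ka_true * q / (1 + ka_true * q)
      ints <- apply_noise(gaussian_band(wavelengths, peak, lambda_max, width),
                          cfg$noise_sd)
      emission_spectrum(wavelengths, ints, q, cfg$temperature_K)
    })
    ts <- titration_series("protein", "ligand", spectra)
  })
  attr(ts, "truth") <- list(model = "enhancement", ka = ka_true, f0 = f0,
                            f_inf = f_inf, lambda_max = lambda_max)
  ts
}

#' Generate a control/treated pair of CETSA melt curves
#'
#' Descending sigmoids with midpoints `tm_control` and
#' `tm_control + delta_tm` on the supplied temperature grid (default: the
#' standard seven-point CETSA gradient 43.5--54.0 deg C); soluble fractions
#' lie in [0,1] before noise.
#'
#' @param tm_control Control melting midpoint, deg C.
#' @param delta_tm Planted ligand-induced shift, deg C.
#' @param temps Temperature grid, strictly increasing, >= 4 points.
#' @param cfg A [sim_config()].
#' @param slope Sigmoid steepness parameter, deg C.
#' @return List with `control` and `treated` [melt_curve()] objects and the
#'   generating `truth`.
#' @export
gen_melt_table <- function(tm_control, delta_tm,
                           temps = c(43.5, 45.0, 46.8, 48.6, 50.4, 52.2, 54.0),
                           cfg = sim_config(), slope = 1.2) {
  if (length(temps) < 4) stop("need at least 4 temperatures")
  if (any(diff(temps) <= 0)) stop("temps must be strictly increasing")
  frac <- function(tm) 1 / (1 + exp((temps - tm) / slope))
  withr::with_seed(cfg$seed, {
    ctrl <- apply_noise(frac(tm_control), cfg$noise_sd)
    trt <- apply_noise(frac(tm_control + delta_tm), cfg$noise_sd)
  })
  list(control = melt_curve("control", temps, ctrl),
       treated = melt_curve("treated", temps, trt),
       truth = list(tm_control = tm_control, delta_tm = delta_tm,
                    slope = slope))
}

#' Generate DEG tables with a planted consensus overlap
#'
#' Builds one DEG table per exposure condition plus a disease gene list such
#' that applying the strict filter (`|log2fc| > 1`, `p < 0.05`) to every
#' table and intersecting with the disease list returns exactly
#' `planted_overlap`. Planted genes pass in all conditions and appear in the
#' disease list; each background gene fails at least one criterion in at
#' least one condition (or is withheld from the disease list).
#'
#' @param n_genes Size of the gene universe (>= number planted).
#' @param planted_overlap Character vector of planted consensus symbols.
#' @param n_conditions Number of exposure conditions (>= 1).
#' @param cfg A [sim_config()].
#' @return List: `deg_tables` (named list of data frames), `disease_genes`
#'   (character), `truth`.
#' @export
gen_deg_tables <- function(n_genes, planted_overlap, n_conditions = 5,
                           cfg = sim_config()) {
  n_planted <- length(planted_overlap)
  if (n_genes < n_planted) stop("n_genes must be >= number of planted genes")
  if (n_conditions < 1) stop("need at least one condition")
  n_bg <- n_genes - n_planted
  background <- sprintf("GENE%04d", seq_len(n_bg))
  universe <- c(planted_overlap, background)
  withr::with_seed(cfg$seed, {
    # condition in which each background gene is forced to fail
    fail_cond <- if (n_bg) sample(n_conditions, n_bg, replace = TRUE) else integer()
    deg_tables <- lapply(seq_len(n_conditions), function(ci) {
      lfc <- stats::rnorm(n_genes, 0, 2)
      p <- stats::runif(n_genes, 1e-6, 1)
      # planted genes pass both strict criteria everywhere
      idx_p <- seq_len(n_planted)
      lfc[idx_p] <- sample(c(-1, 1), n_planted, replace = TRUE) *
        stats::runif(n_planted, 1.5, 4)
      p[idx_p] <- stats::runif(n_planted, 1e-6, 0.01)
      # forced failures: sub-threshold fold change or insignificant p
      if (n_bg) {
        fail_here <- which(fail_cond == ci) + n_planted
        mode_fc <- stats::runif(length(fail_here)) < 0.5
        lfc[fail_here[mode_fc]] <- stats::runif(sum(mode_fc), -0.9, 0.9)
        p[fail_here[!mode_fc]] <- stats::runif(sum(!mode_fc), 0.06, 1)
      }
      data.frame(gene = universe, log2fc = lfc, p = p)
    })
    names(deg_tables) <- sprintf("condition_%d", seq_len(n_conditions))
    # disease list: planted genes plus a random slice of the background
    # (background genes all fail the DEG filter somewhere, so membership
    # here cannot add to the consensus)
    extra <- if (n_bg) sample(background, min(n_bg, max(1, n_bg %/% 3))) else character()
    disease <- c(planted_overlap, extra)
  })
  list(deg_tables = deg_tables, disease_genes = disease,
       truth = list(planted_overlap = planted_overlap))
}

#' Generate a ToxPi metric-table fixture
#'
#' Random identity-transform metrics over `n_chemicals` chemicals in
#' `n_classes` equal classes. If `dominant` is set, that chemical is made
#' strictly best (highest-concern) on every metric, so its overall ToxPi
#' score is exactly 1 and its rank 1.
#'
#' @param n_chemicals Number of chemicals (>= 2).
#' @param dominant Optional chemical name to plant as uniformly worst-case.
#' @param cfg A [sim_config()].
#' @param n_metrics,n_classes Table shape (metrics are dealt round-robin to
#'   classes).
#' @return A [metric_table()] with a `"truth"` attribute.
#' @export
gen_metric_table <- function(n_chemicals, dominant = NULL, cfg = sim_config(),
                             n_metrics = 13, n_classes = 5) {
  if (n_chemicals < 2) stop("min-max scaling needs at least 2 chemicals")
  chems <- sprintf("CHEM%02d", seq_len(n_chemicals))
  if (!is.null(dominant)) chems[1] <- dominant
  withr::with_seed(cfg$seed, {
    vals <- matrix(stats::rnorm(n_chemicals * n_metrics), n_chemicals,
                   n_metrics,
                   dimnames = list(chems, sprintf("metric%02d",
                                                  seq_len(n_metrics))))
    if (!is.null(dominant)) {
      vals[1, ] <- apply(vals[-1, , drop = FALSE], 2, max) +
        stats::runif(n_metrics, 0.5, 1)
    }
  })
  cfg_df <- data.frame(metric = colnames(vals),
                       class = sprintf("class%d",
                                       rep_len(seq_len(n_classes), n_metrics)),
                       transform = "identity",
                       control_value = NA_real_)
  mt <- metric_table(vals, cfg_df)
  attr(mt, "truth") <- list(dominant = dominant)
  mt
}

#' Write a generated bundle of pipeline inputs to disk
#'
#' Emits the CSV dialects the analysis readers consume, plus a sidecar JSON
#' recording the seed and all generating parameters.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @return Invisibly, the list of written file paths.
#' @export
write_synthetic_bundle <- function(dir, cfg = sim_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  truth <- list(seed = cfg$seed, noise_sd = cfg$noise_sd)

  # titration spectra at two temperatures (static quenching, Ksv falling
  # with temperature as for a complex-forming quencher)
  ksv <- c(`298` = 3.57e4, `310` = 2.94e4)
  spec_rows <- do.call(rbind, lapply(names(ksv), function(tk) {
    ts <- gen_titration_series(ksv[[tk]], f0 = 1000,
                               cfg = sim_config(cfg$seed + as.integer(tk),
                                                cfg$noise_sd,
                                                temperature_K = as.numeric(tk)))
    do.call(rbind, lapply(ts$spectra, function(s) {
      data.frame(protein = "PR_LBD", ligand = "BPS",
                 temperature_K = s$temperature,
                 conc_M = s$quencher_conc, wavelength_nm = s$wavelengths,
                 intensity = s$intensities)
    }))
  }))
  paths$titration <- file.path(dir, "titration.csv")
  utils::write.csv(spec_rows, paths$titration, row.names = FALSE)
  truth$titration <- list(ksv_by_T = as.list(ksv), f0 = 1000)

  # CETSA melt tables: control + one treated sample with a planted shift
  mt <- gen_melt_table(48, 1.97, cfg = cfg)
  melt_rows <- rbind(
    data.frame(sample = "Veh", replicate = 1, temp_C = mt$control$temps,
               band_intensity = mt$control$soluble),
    data.frame(sample = "BPA", replicate = 1, temp_C = mt$treated$temps,
               band_intensity = mt$treated$soluble))
  paths$cetsa <- file.path(dir, "cetsa.csv")
  utils::write.csv(melt_rows, paths$cetsa, row.names = FALSE)
  truth$cetsa <- mt$truth

  # DEG tables + disease gene list with planted consensus {PGR, AREG}
  degs <- gen_deg_tables(400, c("AREG", "PGR"), n_conditions = 5, cfg = cfg)
  for (nm in names(degs$deg_tables)) {
    p <- file.path(dir, paste0("deg_", nm, ".csv"))
    utils::write.csv(degs$deg_tables[[nm]], p, row.names = FALSE)
    paths[[paste0("deg_", nm)]] <- p
  }
  paths$disease_genes <- file.path(dir, "disease_genes.txt")
  writeLines(degs$disease_genes, paths$disease_genes)
  truth$deg <- degs$truth

  # ToxPi metric table with a planted dominant chemical
  tox <- gen_metric_table(6, dominant = "BPAF", cfg = cfg)
  df <- data.frame(chemical = rownames(tox$values), tox$values,
                   check.names = FALSE)
  paths$toxpi_values <- file.path(dir, "toxpi_metrics.csv")
  utils::write.csv(df, paths$toxpi_values, row.names = FALSE)
  cfgl <- stats::setNames(lapply(seq_len(nrow(tox$config)), function(i) {
    list(class = tox$config$class[[i]], transform = tox$config$transform[[i]])
  }), tox$config$metric)
  paths$toxpi_config <- file.path(dir, "toxpi_config.json")
  jsonlite::write_json(cfgl, paths$toxpi_config, auto_unbox = TRUE)
  truth$toxpi <- attr(tox, "truth")

  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
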