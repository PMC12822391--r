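#' Construct an emission spectrum
#'
#' One steady-state fluorescence emission scan of a protein--ligand mixture at
#' a single quencher (ligand) concentration and temperature. Wavelengths are
#' nanometres, intensities arbitrary units, concentration mol/L, temperature
#' Kelvin.
#'
#' @param wavelengths Numeric vector of emission wavelengths (nm), strictly
#'   increasing, at least 3 points.
#' @param intensities Numeric vector of fluorescence intensities (a.u.),
#'   non-negative, same length as `wavelengths`.
#' @param quencher_conc Quencher concentration in mol/L (>= 0).
#' @param temperature Temperature in K.
#' @return An object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(wavelengths, intensities, quencher_conc,
                              temperature) {
  stopifnot(is.numeric(wavelengths), is.numeric(intensities))
  if (length(wavelengths) != length(intensities)) {
    stop("wavelengths and intensities must have equal length")
  }
  if (length(wavelengths) < 3) {
    stop("an emission spectrum needs at least 3 points")
  }
  if (any(diff(wavelengths) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (!is.numeric(quencher_conc) || length(quencher_conc) != 1 ||
      quencher_conc < 0) {
    stop("quencher_conc must be a single non-negative number (mol/L)")
  }
  structure(
    list(wavelengths = as.numeric(wavelengths),
         intensities = as.numeric(intensities),
         quencher_conc = as.numeric(quencher_conc),
         temperature = as.numeric(temperature)),
    class = "emission_spectrum"
  )
}

#' Construct a titration series
#'
#' A set of emission spectra of one protein--ligand pair across quencher
#' concentrations at a shared temperature. Exactly one spectrum must be the
#' zero-quencher (F0) scan and concentrations must be unique.
#'
#' @param protein,ligand Character names of the system.
#' @param spectra List of [emission_spectrum()] objects sharing one
#'   temperature.
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(protein, ligand, spectra) {
  if (!length(spectra)) stop("spectra must be a non-empty list")
  if (!all(vapply(spectra, inherits, logical(1), "emission_spectrum"))) {
    stop("all spectra must be emission_spectrum objects")
  }
  concs <- vapply(spectra, `[[`, numeric(1), "quencher_conc")
  temps <- vapply(spectra, `[[`, numeric(1), "temperature")
  if (sum(concs == 0) != 1) {
    stop("exactly one spectrum must have quencher_conc = 0 (the F0 scan)")
  }
  if (anyDuplicated(concs)) stop("quencher concentrations must be unique")
  if (length(unique(temps)) != 1) {
    stop("all spectra in a series must share one temperature")
  }
  ord <- order(concs)
  structure(
    list(protein = protein, ligand = ligand, spectra = spectra[ord],
         temperature = temps[[1]]),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  concs <- vapply(x$spectra, `[[`, numeric(1), "quencher_conc")
  cat(sprintf("<titration_series> %s + %s, T = %g K, %d spectra\n",
              x$protein, x$ligand, x$temperature, length(x$spectra)))
  cat("  [Q] (mol/L):", paste(signif(concs, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Locate the emission maximum of a spectrum
#'
#' Returns the wavelength of the global intensity maximum (ties broken toward
#' the smallest wavelength) and the intensity there. For an untreated
#' tryptophan-containing receptor construct this is typically near 335 nm.
#'
#' @param s An [emission_spectrum()].
#' @return Named list with `lambda_max` (nm) and `peak_intensity` (a.u.).
#' @export
characterize_spectrum <- function(s) {
  stopifnot(inherits(s, "emission_spectrum"))
  if (all(s$intensities == 0)) stop("no peak: all intensities are zero")
  i <- which.max(s$intensities)  # which.max returns the first (smallest wl)
  list(lambda_max = s$wavelengths[[i]], peak_intensity = s$intensities[[i]])
}

#' Extract a concentration--intensity series from a titration
#'
#' Reads one intensity per concentration, either at a fixed reference
#' wavelength (the nearest sampled wavelength is used) or at each spectrum's
#' own emission maximum (`lambda_ref = "per-spectrum-max"`). Quench and
#' binding fits downstream conventionally use the control spectrum's
#' wavelength of maximum emission as the fixed reference.
#'
#' @param ts A [titration_series()].
#' @param lambda_ref Numeric wavelength in nm, or `"per-spectrum-max"`.
#' @return Data frame with columns `conc` (mol/L) and `intensity` (a.u.),
#'   ordered by concentration (conc 0 first).
#' @export
extract_intensity_series <- function(ts, lambda_ref = "per-spectrum-max") {
  stopifnot(inherits(ts, "titration_series"))
  concs <- vapply(ts$spectra, `[[`, numeric(1), "quencher_conc")
  if (identical(lambda_ref, "per-spectrum-max")) {
    ints <- vapply(ts$spectra, function(s) {
      characterize_spectrum(s)$peak_intensity
    }, numeric(1))
  } else {
    stopifnot(is.numeric(lambda_ref), length(lambda_ref) == 1)
    ints <- vapply(ts$spectra, function(s) {
      rng <- range(s$wavelengths)
      if (lambda_ref < rng[1] || lambda_ref > rng[2]) {
        stop(sprintf("lambda_ref %.1f nm outside spectral range [%g, %g]",
                     lambda_ref, rng[1], rng[2]))
      }
      s$intensities[[which.min(abs(s$wavelengths - lambda_ref))]]
    }, numeric(1))
  }
  data.frame(conc = concs, intensity = ints)
}

#' Classify a spectral shift
#'
#' Compares control and treated emission-maximum wavelengths. A decrease of at
#' least `threshold` nm is a blue shift, an increase a red shift, anything
#' smaller no shift. Default threshold 2 nm.
#'
#' @param lambda_control,lambda_treated Peak wavelengths in nm.
#' @param threshold Minimal shift in nm counted as significant.
#' @return One of `"blue"`, `"red"`, `"none"`.
#' @export
classify_shift <- function(lambda_control, lambda_treated, threshold = 2) {
  stopifnot(threshold > 0)
  d <- lambda_control - lambda_treated
  if (d >= threshold) "blue" else if (-d >= threshold) "red" else "none"
}

#' Dose--response direction of an intensity series
#'
#' Classifies the intensity-versus-concentration relationship as strictly
#' `"decreasing"` (quenching-like), strictly `"increasing"`
#' (enhancement-like), or `"none"`. Ties within a relative tolerance break
#' monotonicity.
#'
#' @param series Data frame with columns `conc` and `intensity` (as returned
#'   by [extract_intensity_series()]), at least 3 concentrations.
#' @param tol Relative tolerance for tie detection.
#' @return One of `"decreasing"`, `"increasing"`, `"none"`.
#' @export
monotonic_trend <- function(series, tol = 1e-6) {
  series <- as_intensity_series(series)
  if (nrow(series) < 3) stop("monotonic_trend needs at least 3 concentrations")
  x <- series$intensity[order(series$conc)]
  d <- diff(x)
  scale <- pmax(abs(x[-length(x)]), abs(x[-1]), 1e-300)
  eff <- abs(d) / scale > tol  # steps larger than the tie tolerance
  if (all(eff) && all(d < 0)) return("decreasing")
  if (all(eff) && all(d > 0)) return("increasing")
  "none"
}

# Coerce a 2-column conc/intensity object (data.frame or named list) to the
# canonical series layout used by the fitting routines.
as_intensity_series <- function(series) {
  if (is.data.frame(series)) {
    if (!all(c("conc", "intensity") %in% names(series))) {
      stop("series must have columns 'conc' and 'intensity'")
    }
    out <- series[, c("conc", "intensity")]
  } else if (is.numeric(series) && !is.null(names(series))) {
    out <- data.frame(conc = as.numeric(names(series)),
                      intensity = unname(series))
  } else {
    stop("series must be a data.frame(conc, intensity) or a named numeric")
  }
  if (any(!is.finite(out$conc)) || any(!is.finite(out$intensity))) {
    stop("series contains non-finite values")
  }
  if (any(out$conc < 0)) stop("concentrations must be non-negative")
  out[order(out$conc), , drop = FALSE]
}

#' Read titration spectra from a long-format CSV
#'
#' Expected columns: `protein`, `ligand`, `temperature_K`, `conc_M`,
#' `wavelength_nm`, `intensity`. Each (protein, ligand, temperature)
#' combination becomes one [titration_series()]; wavelength grids may differ
#' between spectra and are never interpolated.
#'
#' @param path Path to the CSV file.
#' @return Named list of `titration_series` objects
#'   (`protein.ligand.temperature` keys).
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "ligand", "temperature_K", "conc_M",
            "wavelength_nm", "intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  keys <- interaction(df$protein, df$ligand, df$temperature_K, drop = TRUE)
  out <- lapply(split(df, keys), function(g) {
    specs <- lapply(split(g, g$conc_M), function(sp) {
      sp <- sp[order(sp$wavelength_nm), ]
      emission_spectrum(sp$wavelength_nm, sp$intensity,
                        sp$conc_M[[1]], sp$temperature_K[[1]])
    })
    titration_series(g$protein[[1]], g$ligand[[1]], unname(specs))
  })
  out
}
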