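# Cellular thermal shift assay (CETSA) analysis: normalization of soluble-
# protein band intensities, descending-sigmoid melt-curve fitting, Tm50 and
# ligand-induced delta-Tm50, and single-temperature stabilization folds.
# Temperatures are degrees Celsius throughout this module.

#' Construct a CETSA melt curve
#'
#' Soluble-protein band intensity versus denaturation temperature for one
#' sample. At least four strictly increasing temperatures are required.
#'
#' @param sample Sample name.
#' @param temps Numeric vector of temperatures (deg C), strictly increasing,
#'   length >= 4.
#' @param soluble Numeric vector of band intensities (>= 0), same length.
#' @return Object of class `melt_curve`.
#' @export
melt_curve <- function(sample, temps, soluble) {
  if (length(temps) < 4) stop("a melt curve needs at least 4 temperatures")
  if (length(temps) != length(soluble)) {
    stop("temps and soluble must have equal length")
  }
  if (any(diff(temps) <= 0)) stop("temps must be strictly increasing")
  if (any(soluble < 0)) stop("band intensities must be non-negative")
  structure(list(sample = sample, temps = as.numeric(temps),
                 soluble = as.numeric(soluble)),
            class = "melt_curve")
}

#' Normalize a melt curve to its lowest-temperature band
#'
#' Divides every band intensity by the lowest-temperature value, so the first
#' point becomes 1 (the usual densitometry convention). Idempotent.
#'
#' @param curve A [melt_curve()].
#' @return A normalized `melt_curve`.
#' @export
normalize_melt <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  if (curve$soluble[[1]] <= 0) {
    stop("cannot normalize: lowest-temperature band intensity is not positive")
  }
  melt_curve(curve$sample, curve$temps, curve$soluble / curve$soluble[[1]])
}

#' Fit a descending sigmoid melt curve
#'
#' Fits `f(T) = bottom + (top - bottom) / (1 + exp((T - tm50)/slope))` by
#' bounded Levenberg--Marquardt least squares. `tm50` is the sigmoid
#' midpoint, the temperature at which the soluble fraction crosses
#' `(top + bottom)/2` — i.e. where half of the initially soluble protein has
#' precipitated. The linearly interpolated 50%-of-range crossing is reported
#' alongside for comparison with the midpoint definition. Top and bottom are
#' free within [-0.2, 1.5] (densitometry rarely reaches exactly 0 or 1).
#'
#' @param curve A normalized [melt_curve()] (see [normalize_melt()]),
#'   spanning a decline (last value below first).
#' @return Object of class `melt_fit`: `sample`, `tm50` (deg C), `slope`
#'   (deg C, > 0 for a descending curve), `top`, `bottom`, `r2`,
#'   `tm50_interpolated`.
#' @export
fit_melt_curve <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  Tt <- curve$temps
  y <- curve$soluble
  if (y[[length(y)]] >= y[[1]]) {
    stop("no melt transition: curve does not decline from first to last point")
  }
  half <- (max(y) + min(y)) / 2
  start <- c(top = max(y), bottom = min(y),
             tm50 = Tt[[which.min(abs(y - half))]], slope = 1)
  sigmoid <- function(p) p[["bottom"]] +
    (p[["top"]] - p[["bottom"]]) / (1 + exp((Tt - p[["tm50"]]) / p[["slope"]]))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = function(p) y - sigmoid(p),
      lower = c(top = -0.2, bottom = -0.2, tm50 = min(Tt), slope = 0.01),
      upper = c(top = 1.5, bottom = 1.5, tm50 = max(Tt), slope = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("melt-curve fit did not converge: ",
                             conditionMessage(e))
  )
  if (fit$info < 1 || fit$info > 4) {
    stop("melt-curve fit did not converge: ", fit$message)
  }
  p <- as.list(fit$par)
  resid <- y - sigmoid(fit$par)
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  # linear interpolation of the 50%-of-fitted-range crossing, for comparison
  mid <- (p$top + p$bottom) / 2
  cross <- NA_real_
  below <- which(y <= mid)
  if (length(below) && below[[1]] > 1) {
    i <- below[[1]]
    cross <- Tt[i - 1] + (mid - y[i - 1]) * (Tt[i] - Tt[i - 1]) / (y[i] - y[i - 1])
  }
  structure(
    list(sample = curve$sample, tm50 = p$tm50, slope = p$slope,
         top = p$top, bottom = p$bottom, r2 = r2,
         tm50_interpolated = cross),
    class = "melt_fit"
  )
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> %s: Tm50 = %.2f degC (slope %.2f, top %.2f, bottom %.2f, r2 %.4f)\n",
              x$sample, x$tm50, x$slope, x$top, x$bottom, x$r2))
  invisible(x)
}

#' Ligand-induced thermal shift
#'
#' `delta_tm50 = treated Tm50 - control Tm50`; positive values mean the
#' ligand stabilizes the protein against thermal precipitation.
#'
#' @param treated,control [fit_melt_curve()] results.
#' @return Shift in deg C.
#' @export
delta_tm50 <- function(treated, control) {
  stopifnot(inherits(treated, "melt_fit"), inherits(control, "melt_fit"))
  treated$tm50 - control$tm50
}

#' Single-temperature (isothermal) stabilization fold
#'
#' Ratio of treated to control soluble band intensity after heating both to
#' one challenge temperature (46 deg C in the xenograft thermal-shift
#' protocol). Values above 1 indicate ligand-induced stabilization.
#'
#' @param treated_band,control_band Band intensities; `control_band` > 0.
#' @return Fold stabilization.
#' @export
isothermal_stabilization <- function(treated_band, control_band) {
  if (any(control_band <= 0)) stop("control band intensity must be positive")
  treated_band / control_band
}

#' Fit melt curves for a CSV of CETSA band intensities
#'
#' Reads `sample, replicate, temp_C, band_intensity`, averages replicates per
#' temperature, normalizes each sample to its lowest-temperature band, fits
#' the descending sigmoid, and reports per-sample Tm50 plus delta-Tm50
#' against a named control.
#'
#' @param path CSV path.
#' @param control Name of the control sample (default `"Veh"`).
#' @return Data frame: `sample`, `tm50`, `slope`, `top`, `bottom`, `r2`,
#'   `delta_tm50`.
#' @export
cetsa_analysis <- function(path, control = "Veh") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "temp_C", "band_intensity")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  }
  fits <- lapply(split(df, df$sample), function(g) {
    agg <- stats::aggregate(band_intensity ~ temp_C, data = g, FUN = mean)
    agg <- agg[order(agg$temp_C), ]
    fit_melt_curve(normalize_melt(
      melt_curve(g$sample[[1]], agg$temp_C, agg$band_intensity)))
  })
  if (!control %in% names(fits)) {
    stop(sprintf("control sample '%s' not found in %s", control, path))
  }
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(sample = f$sample, tm50 = f$tm50, slope = f$slope,
               top = f$top, bottom = f$bottom, r2 = f$r2)
  }))
  out$delta_tm50 <- out$tm50 - fits[[control]]$tm50
  rownames(out) <- NULL
  out
}
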