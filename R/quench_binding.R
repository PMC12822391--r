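# Quenching and binding-constant estimation from concentration--intensity
# series. Three estimators:
#   Stern-Volmer       F0/F = 1 + Ksv[Q] = 1 + kq*tau0*[Q]   (quenching)
#   double-log plot    log10((F0-F)/F) = log10(Ka) + n*log10([Q])
#   double-reciprocal  (Finf-F0)/(Fx-F0) = 1 + 1/(Ka[Q])     (enhancement)
# Concentrations are mol/L throughout; constants are reported both raw and in
# the conventional x1e4 / x1e12 scalings.

#' Stern--Volmer quenching fit
#'
#' Fits `F0/F = 1 + Ksv [Q]` by least squares through the origin on the
#' transformed response `F0/F - 1` (the model has no free intercept), and
#' derives the bimolecular quenching rate constant `kq = Ksv / tau0`. A free-
#' intercept fit of the same transform is attached as a diagnostic but is not
#' used for the reported constants.
#'
#' @param series Data frame (`conc`, `intensity`) or named numeric vector of
#'   intensities keyed by concentration (mol/L); must include conc 0 (F0) plus
#'   at least 3 nonzero concentrations, all intensities positive.
#' @param temperature Temperature in K.
#' @param tau0 Unquenched fluorophore lifetime in seconds (default 1e-8 s,
#'   the canonical biopolymer fluorescence lifetime).
#' @param tol Relative tolerance above F0 at which a point is flagged as
#'   enhancement rather than quenching.
#' @return Object of class `quench_fit` with elements `ksv` (L/mol), `kq`
#'   (L mol^-1 s^-1), `r2`, `n_points`, `temperature`, `tau0`,
#'   `free_intercept` (diagnostic slope/intercept), plus `ksv_1e4`/`kq_1e12`.
#' @export
stern_volmer_fit <- function(series, temperature, tau0 = 1e-8, tol = 1e-6) {
  s <- as_intensity_series(series)
  f0 <- s$intensity[s$conc == 0]
  if (length(f0) != 1) stop("series must contain exactly one conc = 0 point (F0)")
  if (f0 <= 0) stop("F0 must be positive")
  q <- s$conc[s$conc > 0]
  f <- s$intensity[s$conc > 0]
  if (length(q) < 3) stop("need at least 3 nonzero concentrations")
  if (any(f <= 0)) stop("all intensities must be positive")
  if (any(f >= f0 * (1 + tol))) {
    stop("enhancement-like, Stern-Volmer invalid: intensity exceeds F0 at Q > 0")
  }
  y <- f0 / f - 1
  ksv <- sum(q * y) / sum(q^2)            # through-origin least squares
  ss_res <- sum((y - ksv * q)^2)
  r2 <- if (sum(y^2) > 0) 1 - ss_res / sum(y^2) else 1
  diag_fit <- stats::lm(y ~ q)
  structure(
    list(ksv = ksv, kq = ksv / tau0, r2 = r2, n_points = length(q),
         temperature = temperature, tau0 = tau0,
         ksv_1e4 = ksv / 1e4, kq_1e12 = ksv / tau0 / 1e12,
         free_intercept = unname(stats::coef(diag_fit))),
    class = "quench_fit"
  )
}

#' @export
print.quench_fit <- function(x, ...) {
  cat(sprintf(
    "<quench_fit> T = %g K: Ksv = %.3g L/mol (%.2f x1e4), kq = %.3g (%.2f x1e12), r2 = %.4f, n = %d\n",
    x$temperature, x$ksv, x$ksv_1e4, x$kq, x$kq_1e12, x$r2, x$n_points))
  invisible(x)
}

#' Classify the quenching mechanism from two temperatures
#'
#' Static (complex-forming) quenching shows bimolecular rate constants above
#' the diffusion-limited ceiling (`kq_limit`, default 2e10 L mol^-1 s^-1)
#' together with Ksv falling as temperature rises; dynamic (collisional)
#' quenching shows the opposite pattern. Conflicting evidence is reported as
#' indeterminate, with both criteria returned separately.
#'
#' @param fit_T1,fit_T2 [stern_volmer_fit()] results at the lower and higher
#'   temperature respectively.
#' @param kq_limit Maximum diffusion-limited collisional quenching constant.
#' @return List with `mechanism` (`"static"`, `"dynamic"`,
#'   `"indeterminate"`), `kq_exceeds_limit`, `ksv_decreases_with_T`.
#' @export
classify_quenching <- function(fit_T1, fit_T2, kq_limit = 2e10) {
  stopifnot(inherits(fit_T1, "quench_fit"), inherits(fit_T2, "quench_fit"))
  if (!(fit_T1$temperature < fit_T2$temperature)) {
    stop("fit_T1 must be at the lower temperature")
  }
  kq_hi <- fit_T1$kq > kq_limit && fit_T2$kq > kq_limit
  kq_lo <- fit_T1$kq <= kq_limit && fit_T2$kq <= kq_limit
  ksv_down <- fit_T2$ksv < fit_T1$ksv
  mech <- if (kq_hi && ksv_down) {
    "static"
  } else if (kq_lo && !ksv_down && fit_T2$ksv > fit_T1$ksv) {
    "dynamic"
  } else {
    "indeterminate"
  }
  list(mechanism = mech, kq_exceeds_limit = kq_hi,
       ksv_decreases_with_T = ksv_down)
}

#' Double-log (Scatchard-type) binding fit
#'
#' For a quenching series, fits `log10((F0-F)/F) = log10(Ka) + n log10([Q])`
#' by ordinary least squares: the intercept gives the association constant Ka
#' and the slope the apparent number of binding sites n. Logs are base 10
#' (Ka is invariant to the base; n is not — the base is recorded in the
#' result).
#'
#' @inheritParams stern_volmer_fit
#' @return Object of class `binding_fit` with `ka` (L/mol), `n_sites`,
#'   `model = "double_log"`, `r2`, `temperature`, `log_base = 10`, `ka_1e4`.
#' @export
double_log_fit <- function(series, temperature) {
  s <- as_intensity_series(series)
  f0 <- s$intensity[s$conc == 0]
  if (length(f0) != 1) stop("series must contain exactly one conc = 0 point (F0)")
  q <- s$conc[s$conc > 0]
  f <- s$intensity[s$conc > 0]
  if (length(q) < 3) stop("need at least 3 nonzero concentrations")
  if (any(f >= f0)) stop("not a quenching series: F >= F0 at some Q > 0")
  if (any(f <= 0)) stop("all intensities must be positive")
  x <- log10(q)
  y <- log10((f0 - f) / f)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  structure(
    list(ka = 10^co[[1]], n_sites = co[[2]], model = "double_log",
         r2 = r_squared(y, stats::fitted(fit)), temperature = temperature,
         log_base = 10, ka_1e4 = 10^co[[1]] / 1e4),
    class = "binding_fit"
  )
}

#' Fluorescence-enhancement binding fit
#'
#' For a series whose intensity rises toward saturation, fits the double-
#' reciprocal linearization of `(Finf - F0)/(Fx - F0) = 1 + 1/(Ka [Q])`:
#' regressing `1/(Fx - F0)` on `1/[Q]` gives intercept `a = 1/(Finf - F0)`
#' and slope `b = 1/(Ka (Finf - F0))`, whence `Ka = a/b` and
#' `Finf = F0 + 1/a`.
#'
#' @inheritParams stern_volmer_fit
#' @return Object of class `binding_fit` with `ka`, `f_inf`,
#'   `model = "enhancement"`, `r2`, `temperature`, `ka_1e4` (`n_sites` is not
#'   defined for this model and is `NA`).
#' @export
enhancement_fit <- function(series, temperature) {
  s <- as_intensity_series(series)
  f0 <- s$intensity[s$conc == 0]
  if (length(f0) != 1) stop("series must contain exactly one conc = 0 point (F0)")
  q <- s$conc[s$conc > 0]
  f <- s$intensity[s$conc > 0]
  if (length(q) < 3) stop("need at least 3 nonzero concentrations")
  if (any(f <= f0)) stop("not an enhancement series: Fx <= F0 at some Q > 0")
  x <- 1 / q
  y <- 1 / (f - f0)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  a <- co[[1]]; b <- co[[2]]
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) {
    stop("no saturating enhancement: double-reciprocal fit gave a <= 0 or b <= 0")
  }
  structure(
    list(ka = a / b, f_inf = f0 + 1 / a, n_sites = NA_real_,
         model = "enhancement", r2 = r_squared(y, stats::fitted(fit)),
         temperature = temperature, ka_1e4 = a / b / 1e4),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit:%s> T = %g K: Ka = %.4g L/mol (%.2f x1e4)",
              x$model, x$temperature, x$ka, x$ka_1e4))
  if (identical(x$model, "double_log")) cat(sprintf(", n = %.3f", x$n_sites))
  cat(sprintf(", r2 = %.4f\n", x$r2))
  invisible(x)
}

#' Fit a binding model chosen by the dose--response direction
#'
#' Dispatches on [monotonic_trend()]: a strictly decreasing series goes to the
#' quenching double-log fit, a strictly increasing one to the enhancement
#' fit; mixed series are rejected.
#'
#' @inheritParams stern_volmer_fit
#' @return A `binding_fit`.
#' @export
fit_binding <- function(series, temperature) {
  trend <- monotonic_trend(as_intensity_series(series))
  switch(trend,
    decreasing = double_log_fit(series, temperature),
    increasing = enhancement_fit(series, temperature),
    stop("mixed (non-monotone) series: cannot choose a binding model")
  )
}

# coefficient of determination on the (possibly transformed) response
r_squared <- function(y, yhat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum((y - yhat)^2) / ss_tot
}

#' Is a binding constant in the biologically relevant range?
#'
#' Association constants between roughly 1e4 and 1e6 L/mol are considered the
#' optimal range for receptor-mediated endocrine interference: strong enough
#' to compete with endogenous ligands, weak enough to stay reversible. The
#' check is inclusive at both bounds and strict otherwise.
#'
#' @param ka Association constant in L/mol (> 0).
#' @param lo,hi Range bounds in L/mol.
#' @return Logical.
#' @export
ka_in_optimal_range <- function(ka, lo = 1e4, hi = 1e6) {
  stopifnot(ka > 0)
  ka >= lo & ka <= hi
}
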