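test_that("Stern-Volmer fit recovers printed and synthetic constants exactly", {
  # noiseless series built at a printed constant
  qf <- stern_volmer_fit(static_series(0.76e4), 298)
  expect_equal(qf$ksv, 0.76e4, tolerance = 1e-9)
  expect_equal(qf$kq, 0.76e12, tolerance = 1e-9)
  expect_equal(qf$ksv_1e4, 0.76, tolerance = 1e-9)
  expect_equal(qf$kq_1e12, 0.76, tolerance = 1e-9)
  # round-trip at another constant
  qf2 <- stern_volmer_fit(static_series(3.57e4), 298)
  expect_equal(qf2$ksv, 3.57e4, tolerance = 1e-6)
  expect_gt(qf2$r2, 1 - 1e-9)
})

test_that("constant intensity gives zero quenching; enhancement is rejected", {
  flat <- data.frame(conc = ladder, intensity = rep(1000, 6))
  expect_equal(stern_volmer_fit(flat, 298)$ksv, 0)
  expect_error(stern_volmer_fit(enh_series(1e5), 298), "enhancement-like")
  expect_error(stern_volmer_fit(static_series(1e4)[1:3, ], 298), "at least 3")
})

test_that("kq/ksv = 1/tau0 holds exactly for any fit", {
  for (K in c(0.38e4, 1.01e4, 2.94e4)) {
    qf <- stern_volmer_fit(static_series(K), 310, tau0 = 1e-8)
    expect_identical(qf$kq, qf$ksv / 1e-8)
  }
})

test_that("quenching mechanism classification follows both criteria", {
  lo <- stern_volmer_fit(static_series(3.57e4), 298)
  hi <- stern_volmer_fit(static_series(2.94e4), 310)
  out <- classify_quenching(lo, hi)
  expect_identical(out$mechanism, "static")
  expect_true(out$kq_exceeds_limit)
  expect_true(out$ksv_decreases_with_T)
  # collisional pattern: small kq (via long tau0), Ksv rising with T
  lo2 <- stern_volmer_fit(static_series(1e4), 298, tau0 = 1e-5)
  hi2 <- stern_volmer_fit(static_series(2e4), 310, tau0 = 1e-5)
  expect_identical(classify_quenching(lo2, hi2)$mechanism, "dynamic")
  # conflicting evidence: kq over the limit but Ksv rising
  lo3 <- stern_volmer_fit(static_series(1e4), 298)
  hi3 <- stern_volmer_fit(static_series(2e4), 310)
  expect_identical(classify_quenching(lo3, hi3)$mechanism, "indeterminate")
  expect_error(classify_quenching(hi, lo), "lower temperature")
})

test_that("double-log fit recovers Ka and n for single-site static series", {
  # algebraic identity: F = F0/(1+Ka*Q) implies intercept log10(Ka), slope 1
  bf <- double_log_fit(static_series(1e5), 298)
  expect_equal(bf$ka, 1e5, tolerance = 1e-6)
  expect_equal(bf$n_sites, 1, tolerance = 1e-6)
  bf2 <- double_log_fit(static_series(10.51e4), 298)
  expect_equal(bf2$ka, 10.51e4, tolerance = 1e-6)
  expect_identical(bf$model, "double_log")
  expect_identical(bf$log_base, 10)
})

test_that("double-log fit rejects non-quenching or underdetermined input", {
  expect_error(double_log_fit(static_series(1e4)[1:3, ], 298), "at least 3")
  expect_error(double_log_fit(enh_series(1e4), 298), "not a quenching series")
})

test_that("enhancement fit recovers Ka and the saturation intensity", {
  bf <- enhancement_fit(enh_series(4.16e4, 1000, 2000), 298)
  expect_equal(bf$ka, 4.16e4, tolerance = 1e-6)
  expect_equal(bf$f_inf, 2000, tolerance = 1e-6)
  expect_true(is.na(bf$n_sites))
  flat <- data.frame(conc = ladder, intensity = rep(1000, 6))
  expect_error(enhancement_fit(flat, 298), "not an enhancement series")
})

test_that("enhancement Ka recovery degrades gracefully with noise", {
  med_err <- function(noise_sd) {
    errs <- vapply(1:200, function(seed) {
      ts <- gen_enhancement_series(1e5, 1000, 2000,
                                   cfg = sim_config(seed, noise_sd))
      ser <- extract_intensity_series(ts, 335)
      # noise occasionally breaks the Fx > F0 precondition; such series are
      # rejected by design and recorded as NA
      tryCatch(abs(enhancement_fit(ser, 298)$ka - 1e5) / 1e5,
               error = function(e) NA_real_)
    }, numeric(1))
    median(errs, na.rm = TRUE)
  }
  # the double-reciprocal transform leans hard on the lowest concentration
  # (largest 1/Q), so Ka error amplifies noise roughly 20-fold; at 0.1%
  # intensity noise recovery is comfortably within 5%
  expect_lt(med_err(0.001), 0.05)
  expect_lt(med_err(0.01), 0.5)
})

test_that("Stern-Volmer and double-log agree on single-site static series", {
  for (K in c(0.54e4, 1.41e4, 4.16e4)) {
    ser <- static_series(K)
    expect_equal(stern_volmer_fit(ser, 298)$ksv,
                 double_log_fit(ser, 298)$ka, tolerance = 1e-6)
    expect_equal(double_log_fit(ser, 298)$n_sites, 1, tolerance = 1e-6)
  }
})

test_that("fits are invariant to uniform intensity rescaling", {
  ser <- static_series(2e4)
  scaled <- transform(ser, intensity = intensity * 123.4)
  expect_equal(stern_volmer_fit(ser, 298)$ksv,
               stern_volmer_fit(scaled, 298)$ksv, tolerance = 1e-9)
  expect_equal(double_log_fit(ser, 298)$ka,
               double_log_fit(scaled, 298)$ka, tolerance = 1e-9)
  enh <- enh_series(3e4)
  enh_scaled <- transform(enh, intensity = intensity * 123.4)
  expect_equal(enhancement_fit(enh, 298)$ka,
               enhancement_fit(enh_scaled, 298)$ka, tolerance = 1e-9)
})

test_that("model selection dispatches on the dose-response direction", {
  expect_identical(fit_binding(static_series(1e4), 298)$model, "double_log")
  expect_identical(fit_binding(enh_series(1e4), 298)$model, "enhancement")
  mixed <- data.frame(conc = ladder, intensity = c(10, 9, 11, 8, 7, 6))
  expect_error(fit_binding(mixed, 298), "mixed")
})

test_that("optimal-range check is inclusive at bounds and strict outside", {
  expect_true(ka_in_optimal_range(4.16e4))
  expect_true(ka_in_optimal_range(1e4))
  expect_true(ka_in_optimal_range(1e6))
  expect_false(ka_in_optimal_range(0.98e4))
  expect_false(ka_in_optimal_range(1.0001e6))
  expect_error(ka_in_optimal_range(-1))
})
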