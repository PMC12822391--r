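test_that("metric transforms orient values toward concern", {
  v <- c(BPA = -7.8, BPAF = -8.6)
  expect_equal(transform_metric(v, "negate"), c(BPA = 7.8, BPAF = 8.6))
  expect_equal(transform_metric(c(BPAF = 11.20), "absdiff_vs_control", 31.55),
               c(BPAF = 20.35))
  expect_identical(transform_metric(v, "identity"), v)
  expect_error(transform_metric(v, "absdiff_vs_control"), "control_value")
  expect_error(transform_metric(v, "sqrt"), "unknown transform")
})

test_that("min-max scaling matches a hand-computed example", {
  negated <- c(BPA = 7.8, BPS = 7.6, BPE = 7.6, BPF = 7.6, BPB = 7.9,
               BPAF = 8.6)
  got <- minmax_scale(negated)
  expect_equal(got, c(BPA = 0.2, BPS = 0, BPE = 0, BPF = 0, BPB = 0.3,
                      BPAF = 1.0), tolerance = 1e-9)
  expect_equal(minmax_scale(c(a = 5, b = 5, c = 5)), c(a = 0, b = 0, c = 0))
  expect_equal(sort(minmax_scale(c(x = 1, y = 2))), c(x = 0, y = 1),
               ignore_attr = TRUE)
  expect_error(minmax_scale(c(a = 1)), "at least 2")
  # missing values contribute nothing
  expect_equal(minmax_scale(c(a = 1, b = 3, c = NA))[["c"]], 0)
})

test_that("toxpi_scores enforces weights and produces bounded scores", {
  mt <- gen_metric_table(4, cfg = sim_config(1))
  res <- toxpi_scores(mt)
  sl <- as.matrix(res[, grep("^slice_", names(res))])
  expect_true(all(sl >= 0 & sl <= 1))
  expect_true(all(res$overall >= 0 & res$overall <= 1))
  expect_setequal(res$rank, 1:4)
  w <- attr(res, "weights")
  expect_equal(sum(w), 1)
  bad_w <- setNames(rep(0.3, 5), sprintf("class%d", 1:5))
  expect_error(toxpi_scores(mt, weights = bad_w), "sum to 1")
  expect_error(toxpi_scores(mt, weights = c(class1 = 1)), "missing")
})

test_that("overall equals the weighted sum of slice scores", {
  mt <- gen_metric_table(5, cfg = sim_config(8))
  res <- toxpi_scores(mt)
  w <- attr(res, "weights")
  sl <- as.matrix(res[, paste0("slice_", names(w))])
  expect_equal(as.numeric(sl %*% w), res$overall)
})

test_that("degenerate metrics score zero for every chemical", {
  vals <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("m1", "m2")))
  cfg <- data.frame(metric = c("m1", "m2"), class = "c1",
                    transform = "identity", control_value = NA)
  res <- toxpi_scores(metric_table(vals, cfg))
  expect_true(all(res$overall == 0))
})

test_that("ranking is descending with lexicographic tie-break", {
  r <- rank_profiles(data.frame(chemical = c("B", "A"), overall = c(0.5, 0.9)))
  expect_identical(r$chemical, c("A", "B"))
  tied <- rank_profiles(data.frame(chemical = c("Z", "M", "A"),
                                   overall = 0.5))
  expect_identical(tied$chemical, c("A", "M", "Z"))
  expect_identical(tied$rank, 1:3)
})

test_that("scores are invariant to positive affine transforms of raw metrics", {
  mt <- gen_metric_table(6, cfg = sim_config(10))
  base <- toxpi_scores(mt)
  vals2 <- mt$values
  vals2[, 1] <- 3.7 * vals2[, 1] + 11
  vals2[, 5] <- 0.2 * vals2[, 5] - 4
  alt <- toxpi_scores(metric_table(vals2, mt$config))
  expect_equal(alt$overall, base$overall)
  expect_identical(alt$chemical, base$chemical)
})

test_that("improving one chemical on one metric never lowers its overall score", {
  mt <- gen_metric_table(6, cfg = sim_config(12))
  base <- toxpi_scores(mt)
  for (j in c(1, 7, 13)) {
    vals2 <- mt$values
    vals2["CHEM03", j] <- vals2["CHEM03", j] + 1
    res2 <- toxpi_scores(metric_table(vals2, mt$config))
    expect_gte(res2$overall[res2$chemical == "CHEM03"],
               base$overall[base$chemical == "CHEM03"])
  }
})

test_that("metric insertion order does not change the ranking", {
  mt <- gen_metric_table(6, cfg = sim_config(13))
  perm <- sample(ncol(mt$values))
  mt2 <- metric_table(mt$values[, perm], mt$config[perm, ])
  expect_equal(toxpi_scores(mt2)$overall, toxpi_scores(mt)$overall)
  expect_identical(toxpi_scores(mt2)$chemical, toxpi_scores(mt)$chemical)
})

test_that("the bundled 13-metric fixture ranks BPAF first", {
  mt <- bp_toxpi_fixture()
  expect_equal(ncol(mt$values), 13)
  expect_equal(length(unique(mt$config$class)), 5)
  res <- toxpi_scores(mt)  # uniform 20% weights over five classes
  expect_identical(res$chemical[[1]], "BPAF")
  expect_equal(res$rank[[1]], 1L)
})

test_that("metric-table CSV/JSON reader rebuilds the fixture", {
  vals_csv <- system.file("extdata", "toxpi_metrics.csv", package = "bprisk")
  cfg_json <- system.file("extdata", "toxpi_config.json", package = "bprisk")
  mt <- read_metric_table(vals_csv, cfg_json)
  expect_s3_class(mt, "metric_table")
  expect_equal(nrow(mt$values), 6)
})
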