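test_that("energy decompositions validate additivity", {
  bpaf <- list(e_vdw = -36.91, e_ele = -14.92, g_sol_polar = 26.61,
               g_sol_nonpolar = -4.16, g_binding = -29.38)
  expect_true(validate_energy_decomposition(bpaf)$ok)
  bpa <- list(e_vdw = -33.24, e_ele = -15.18, g_sol_polar = 23.50,
              g_sol_nonpolar = -3.40, g_binding = -28.32)
  expect_true(validate_energy_decomposition(bpa)$ok)
  off <- bpaf; off$g_binding <- off$g_binding + 0.5
  res <- validate_energy_decomposition(off)
  expect_false(res$ok)
  expect_equal(abs(res$delta), 0.5)
  bad <- bpaf; bad$e_ele <- NA
  expect_error(validate_energy_decomposition(bad), "finite")
})

test_that("all bundled energy rows are additive and rank as expected", {
  en <- bp_energy_decomposition()
  for (i in seq_len(nrow(en))) {
    expect_true(validate_energy_decomposition(en[i, ], tol = 0.01)$ok,
                label = en$chemical[[i]])
  }
  rk <- rank_chemicals_by_value(
    data.frame(chemical = en$chemical, value = en$g_binding))
  expect_identical(rk$chemical, c("BPAF", "BPB", "BPA", "BPF", "BPE", "BPS"))
})

test_that("chemical ranking handles direction, ties and duplicates", {
  dk <- bp_docking()
  rk <- rank_chemicals_by_value(
    data.frame(chemical = dk$chemical, value = dk$score))
  expect_identical(rk$chemical[[1]], "BPAF")
  expect_equal(rk$value[[1]], -8.6)
  # the three -7.6 scores tie and resolve lexicographically
  tied <- rk$chemical[rk$value == -7.6]
  expect_identical(tied, sort(tied))
  allsame <- data.frame(chemical = c("C", "A", "B"), value = 1)
  expect_identical(rank_chemicals_by_value(allsame)$chemical,
                   c("A", "B", "C"))
  expect_error(rank_chemicals_by_value(
    data.frame(chemical = c("A", "A"), value = 1:2)), "duplicate")
})

test_that("secondary-structure sums validate within tolerance", {
  bpaf <- list(alpha_helix = 2.40, beta_sheet = 65.47, beta_turn = 20.93,
               random_coil = 11.20)
  expect_true(validate_secondary_structure(bpaf)$ok)
  ctrl <- list(alpha_helix = 9.39, beta_sheet = 44.64, beta_turn = 14.48,
               random_coil = 31.55)
  r <- validate_secondary_structure(ctrl)
  expect_true(r$ok)
  expect_equal(r$sum, 100.06)
  bad <- validate_secondary_structure(
    list(alpha_helix = 50, beta_sheet = 50, beta_turn = 50,
         random_coil = 50))
  expect_false(bad$ok)
  expect_equal(bad$sum, 200)
})

test_that("all bundled CD rows sum to 100 within 0.1", {
  ss <- bp_secondary_structure()
  for (i in seq_len(nrow(ss))) {
    expect_true(validate_secondary_structure(ss[i, ], tol = 0.1)$ok,
                label = ss$sample[[i]])
  }
})

test_that("secondary-structure deltas reproduce the reported changes", {
  ss <- bp_secondary_structure()
  d <- secondary_structure_delta(ss[ss$sample == "BPAF", ],
                                 ss[ss$sample == "control", ])
  expect_equal(d$delta[d$element == "random_coil"], -20.35)
  expect_equal(d$delta[d$element == "beta_sheet"], 20.83)
  same <- secondary_structure_delta(ss[1, ], ss[1, ])
  expect_true(all(same$delta == 0))
})

test_that("DEG filter applies strict thresholds and flags malformed p-values", {
  recs <- data.frame(
    gene = c("A", "B", "C", "D", "E"),
    log2fc = c(1.0, -1.5, 2.0, 3.0, 2.0),
    p = c(0.01, 0.049, 0.05, 0.001, 2))
  expect_warning(got <- filter_degs(recs), "malformed")
  expect_setequal(got, c("B", "D"))  # A fails |fc| strict, C fails p strict
})

test_that("DEG filter is monotone in both thresholds", {
  d <- gen_deg_tables(200, c("PGR"), 1, sim_config(3))$deg_tables[[1]]
  strict <- filter_degs(d, fc_thresh = 1.5, p_thresh = 0.01)
  loose <- filter_degs(d, fc_thresh = 1, p_thresh = 0.05)
  expect_true(all(strict %in% loose))
})

test_that("gene-set intersection is exact, commutative and idempotent", {
  a <- c("PGR", "AREG", "TP53"); b <- c("AREG", "PGR"); c_ <- c("PGR", "AREG", "ESR1")
  expect_identical(intersect_gene_sets(list(a, b, c_)), c("AREG", "PGR"))
  expect_identical(intersect_gene_sets(list(a, b, c_)),
                   intersect_gene_sets(list(c_, a, b)))
  expect_identical(intersect_gene_sets(list(a, a)), sort(a))
  expect_identical(intersect_gene_sets(list(a, character(0))), character(0))
  # case-sensitive: "pgr" does not match "PGR"
  expect_identical(intersect_gene_sets(list(c("PGR"), c("pgr"))), character(0))
  expect_error(intersect_gene_sets(list(a)), "at least 2")
})

test_that("tumor volume and fold-change helpers compute as defined", {
  expect_equal(tumor_volume(10, 5), 125)
  expect_equal(tumor_volume(3, 3), 27 / 2)
  expect_warning(v <- tumor_volume(5, 10), "width exceeds length")
  expect_equal(v, 5 * 100 / 2)
  expect_error(tumor_volume(5, 0), "positive")
  expect_equal(fold_change_vs_control(1230, 781), 1230 / 781)
  expect_equal(fold_change_vs_control(1230, 781), 1.575, tolerance = 1e-3)
  expect_equal(fold_change_vs_control(2.54, 1), 2.54)
  expect_error(fold_change_vs_control(1, 0), "positive")
})

test_that("table readers validate and normalize their columns", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "deg.csv")
  write.csv(data.frame(gene = "PGR", log2fc = 2, pvalue = 0.01), f,
            row.names = FALSE)
  got <- read_deg_csv(f)
  expect_identical(names(got), c("gene", "log2fc", "p"))
  g <- file.path(dir, "genes.txt")
  writeLines(c("PGR", "", "AREG "), g)
  expect_identical(read_gene_list(g), c("PGR", "AREG"))
  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_energy_csv(bad), "missing columns")
})
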