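test_that("build_default_spec calibrates the stated anchors", {
  spec <- build_default_spec(n = 1000, seed = 3)
  mg <- spec$marginals
  # lognormal R: median exp(meanlog), sdlog^2 = 2 ln(mean/median)
  expect_equal(exp(mg$r$meanlog), 0.046)
  expect_equal(mg$r$sdlog^2, 2 * log(0.054 / 0.046), tolerance = 1e-12)
  # GooF offset + lognormal median
  expect_equal(mg$goof$offset + exp(mg$goof$meanlog), 1.045)
  # shift zero-inflated exponential: P(X <= 0.001) = 0.5 exactly
  p <- mg$shift$zero_fraction +
    (1 - mg$shift$zero_fraction) * pexp(0.001, mg$shift$rate)
  expect_equal(p, 0.5, tolerance = 1e-10)
  # wR factor median equals the anchor ratio
  expect_equal(exp(mg$wr_factor$meanlog), 0.118 / 0.046)
  # quotas are exact integers within n
  expect_true(all(spec$quotas$missing + spec$quotas$malformed +
                    spec$quotas$out_of_range <= spec$n))
  # category weights on each axis sum to one
  expect_equal(sum(spec$category$radiation), 1)
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- build_default_spec(n = 60, seed = 5)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  g1 <- generate_corpus(spec, d1)
  g2 <- generate_corpus(spec, d2)
  expect_identical(g1$ground_truth, g2$ground_truth)
  h1 <- tools::md5sum(g1$files)
  h2 <- tools::md5sum(g2$files)
  expect_identical(unname(h1), unname(h2))
  # a different seed changes the corpus
  g3 <- generate_corpus(build_default_spec(n = 60, seed = 6),
                        file.path(tempdir(), "det3"))
  expect_false(identical(unname(tools::md5sum(g3$files)), unname(h1)))
})

test_that("injection quotas are recovered exactly by the audit", {
  c0 <- shared_corpus()
  tal <- c0$audit$tallies
  q <- c0$spec$quotas
  tagmap <- c(r = "_refine_ls_r_factor_gt", wr = "_refine_ls_wr_factor_ref",
              shift_su = "_refine_ls_shift/su_max",
              rho_max = "_refine_diff_density_max",
              rho_min = "_refine_diff_density_min",
              goof = "_refine_ls_goodness_of_fit_ref",
              theta_max = "_diffrn_reflns_theta_max")
  for (m in q$metric) {
    row <- tal[tal$tag == tagmap[[m]], ]
    qr <- q[q$metric == m, ]
    expect_equal(row$n_missing, qr$missing, info = m)
    expect_equal(row$n_non_numeric, qr$malformed, info = m)
    expect_equal(row$n_out_of_range, qr$out_of_range, info = m)
    expect_equal(row$n_accepted,
                 c0$spec$n - qr$missing - qr$malformed - qr$out_of_range,
                 info = m)
  }
  # injection flags in the ground truth match the quotas exactly
  for (m in q$metric) {
    flags <- table(factor(c0$gen$ground_truth[[paste0("inj_", m)]],
                          levels = c("none", "missing", "malformed",
                                     "out_of_range")))
    qr <- q[q$metric == m, ]
    expect_equal(unname(flags[["missing"]]), qr$missing)
    expect_equal(unname(flags[["malformed"]]), qr$malformed)
    expect_equal(unname(flags[["out_of_range"]]), qr$out_of_range)
  }
})

test_that("accepted values equal ground truth at uninjected positions", {
  c0 <- shared_corpus()
  gt <- c0$gen$ground_truth
  rec <- c0$audit$records
  expect_identical(rec$identifier, gt$identifier)
  for (m in c("r", "wr", "goof", "shift_su", "rho_max", "rho_min",
              "theta_max")) {
    clean <- gt[[paste0("inj_", m)]] == "none"
    expect_equal(rec[[m]][clean], gt[[m]][clean], info = m)
    expect_true(all(is.na(rec[[m]][!clean])), info = m)
  }
  # Zmax derived from atom sites matches the generator's
  expect_equal(rec$z_max, gt$z_max)
})

test_that("generator guarantees: wR > R, signs, validity truncation", {
  c0 <- shared_corpus()
  gt <- c0$gen$ground_truth
  expect_true(all(gt$wr > gt$r))
  expect_true(all(gt$rho_min < 0))
  expect_true(all(gt$rho_max > 0 & gt$rho_max < 118))
  expect_true(all(gt$r > 0 & gt$r < 1))
  expect_true(all(gt$wr < 1))
  expect_true(all(gt$goof > 0 & gt$goof < 20))
  expect_true(all(gt$shift_su > 0 & gt$shift_su < 15))
  expect_true(all(gt$theta_max > 0 & gt$theta_max < 90))
  # theta bimodality tied to wavelength: Mo thetas low, Cu thetas high
  mo <- !is.na(gt$wavelength) & gt$wavelength == 0.71073 &
    gt$inj_theta_max == "none"
  cu <- !is.na(gt$wavelength) & gt$wavelength == 1.54184 &
    gt$inj_theta_max == "none"
  expect_true(all(gt$theta_max[mo] < 45))
  expect_true(all(gt$theta_max[cu] > 45))
})

test_that("classification recovers ground-truth labels with zero errors", {
  c0 <- shared_corpus()
  gt <- c0$gen$ground_truth
  labels <- categorize_entries(c0$entries)
  expect_identical(labels$identifier, gt$identifier)
  expect_identical(labels$chemistry, gt$chemistry)
  expect_identical(labels$disordered, gt$disordered)
  expect_identical(labels$radiation, gt$radiation)
  expect_identical(labels$pressure, gt$pressure)
})

test_that("rare radiation sources are recovered from a weighted spec", {
  spec <- build_default_spec(n = 150, seed = 21)
  spec$category$radiation <- c(xray = 0.5, neutron = 0.3, electron = 0.2)
  g <- generate_corpus(spec, file.path(tempdir(), "rad150"))
  entries <- unlist(lapply(g$files, read_cif_blocks), recursive = FALSE)
  labels <- categorize_entries(entries)
  expect_identical(labels$radiation, g$ground_truth$radiation)
  expect_true(all(c("xray", "neutron", "electron") %in% labels$radiation))
  # aspherical heuristic picks up the generator's details text
  spec2 <- build_default_spec(n = 80, seed = 22)
  spec2$category$aspherical_fraction <- 0.5
  g2 <- generate_corpus(spec2, file.path(tempdir(), "asp80"))
  entries2 <- unlist(lapply(g2$files, read_cif_blocks), recursive = FALSE)
  labels2 <- categorize_entries(entries2)
  expect_identical(labels2$refinement_type, g2$ground_truth$refinement_type)
  expect_true(any(labels2$refinement_type == "aspherical"))
})

test_that("sample medians track the calibrated population (coarse, small n)", {
  c0 <- shared_corpus()
  rec <- c0$audit$records
  # n = 400 gives wide sampling error; this is a sanity net, the tight
  # n = 20000 recovery check lives in the acceptance suite
  expect_equal(median(rec$r, na.rm = TRUE), 0.046, tolerance = 0.15)
  expect_equal(median(rec$goof, na.rm = TRUE), 1.045, tolerance = 0.02)
  expect_equal(median(rec$wr, na.rm = TRUE), 0.118, tolerance = 0.15)
  # category mixture within binomial error (3 sigma)
  gt <- c0$gen$ground_truth
  p_hat <- mean(gt$chemistry == "organic")
  se <- sqrt(0.45 * 0.55 / nrow(gt))
  expect_lt(abs(p_hat - 0.45), 3 * se + 1e-9)
})
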