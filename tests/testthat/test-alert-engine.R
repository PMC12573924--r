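cfg <- alert_thresholds()

test_that("severity ordering and aggregation", {
  expect_true(alert_severity("A") > alert_severity("B"))
  expect_true(alert_severity("B") > alert_severity("C"))
  expect_true(alert_severity("C") > alert_severity("none"))
  expect_identical(worst_alert(c("none", "C", "B")), "B")
  expect_identical(worst_alert(character(0)), "none")
  expect_error(alert_severity("G"), "unknown")
})

test_that("residual-density alert follows the DTEST scheme", {
  # Zmax=6: thresholds C 0.45, B 0.6, A 1.2
  expect_identical(residual_density_alert(1.3, z_max = 6, cfg = cfg), "A")
  expect_identical(residual_density_alert(1.0, z_max = 6, cfg = cfg), "B")
  expect_identical(residual_density_alert(0.5, z_max = 6, cfg = cfg), "C")
  expect_identical(residual_density_alert(0.4, z_max = 6, cfg = cfg), "none")
  # Zmax=80: 5.0 < 0.075*80 = 6.0, no alert even with a deep minimum
  expect_identical(residual_density_alert(5.0, -4.0, 80, cfg), "none")
  # Zmax=34: 2.55 < 3.0 < 3.4 -> C
  expect_identical(residual_density_alert(3.0, z_max = 34, cfg = cfg), "C")
  # the test uses max(rho_max, |rho_min|)
  expect_identical(residual_density_alert(0.1, -1.3, 6, cfg), "A")
  expect_error(residual_density_alert(1, z_max = NA, cfg = cfg), "z_max")
})

test_that("fit-metric alerts use the printed boundaries", {
  rec <- list(r = 0.05, wr = 0.12, goof = 1.0, shift_su = 0.001)
  expect_true(all(fit_metric_alerts(rec, cfg) == "none"))
  expect_identical(fit_metric_alerts(list(r = 0.12), cfg)[["r"]], "C")
  expect_identical(fit_metric_alerts(list(wr = 0.3), cfg)[["wr"]], "C")
  expect_identical(fit_metric_alerts(list(goof = 7.0), cfg)[["goof"]], "A")
  expect_identical(fit_metric_alerts(list(goof = 0.5), cfg)[["goof"]], "B")
  expect_identical(fit_metric_alerts(list(goof = 2.5), cfg)[["goof"]], "C")
  expect_identical(fit_metric_alerts(list(goof = 0.3), cfg)[["goof"]], "A")
  expect_identical(fit_metric_alerts(list(shift_su = 0.5), cfg)[["shift_su"]],
                   "C")
  # absent metrics produce no alert
  expect_true(all(fit_metric_alerts(list(r = NA_real_), cfg) == "none"))
})

test_that("boundary semantics are strict: exact thresholds do not trigger", {
  expect_identical(fit_metric_alerts(list(r = 0.1), cfg)[["r"]], "none")
  expect_identical(fit_metric_alerts(list(wr = 0.25), cfg)[["wr"]], "none")
  expect_identical(fit_metric_alerts(list(goof = 2.0), cfg)[["goof"]], "none")
  expect_identical(fit_metric_alerts(list(goof = 0.8), cfg)[["goof"]], "none")
  expect_identical(fit_metric_alerts(list(shift_su = 0.2), cfg)[["shift_su"]],
                   "none")
  # residual density at exactly 7.5% / 10% / 20% of Zmax
  expect_identical(residual_density_alert(3.0, z_max = 40, cfg = cfg), "none")
  expect_identical(residual_density_alert(4.0, z_max = 40, cfg = cfg), "C")
  expect_identical(residual_density_alert(8.0, z_max = 40, cfg = cfg), "B")
  # resolution exactly at 0.6: strict "below"
  r06 <- resolution_from_bragg(0.71073, asin(0.6 * 0.71073) * 180 / pi)
  expect_equal(r06$sin_theta_over_lambda, 0.6, tolerance = 1e-12)
  expect_identical(resolution_alert(r06, cfg), "none")
})

test_that("resolution alert triggers below 0.6 1/A", {
  mk <- function(sintl) {
    structure(list(d = 1 / (2 * sintl), sin_theta_over_lambda = sintl,
                   source = "computed"), class = "resolution_value")
  }
  expect_identical(resolution_alert(mk(0.70), cfg), "none")
  expect_identical(resolution_alert(mk(0.55), cfg), "C")
})

test_that("alert monotonicity and severity nesting (threshold scan)", {
  # R scan: increasing R never lowers the level
  rs <- seq(0.01, 0.9, by = 0.005)
  lv <- vapply(rs, function(r) fit_metric_alerts(list(r = r), cfg)[["r"]],
               character(1))
  expect_true(all(diff(alert_severity(lv)) >= 0))

  # GooF scan upward from 1: severities are non-decreasing and nested C<B<A
  gs <- seq(1, 8, by = 0.01)
  sev <- alert_severity(vapply(gs, function(g) {
    fit_metric_alerts(list(goof = g), cfg)[["goof"]]
  }, character(1)))
  expect_true(all(diff(sev) >= 0))
  expect_identical(sort(unique(sev)), c(0, 1, 2, 3))
  # downward from 1 likewise
  gs2 <- seq(1, 0.2, by = -0.01)
  sev2 <- alert_severity(vapply(gs2, function(g) {
    fit_metric_alerts(list(goof = g), cfg)[["goof"]]
  }, character(1)))
  expect_true(all(diff(sev2) >= 0))

  # residual density scan at fixed Zmax
  for (zm in c(6, 34, 80)) {
    rhos <- seq(0.01, 0.25 * zm, length.out = 400)
    sevr <- alert_severity(vapply(rhos, function(p) {
      residual_density_alert(p, z_max = zm, cfg = cfg)
    }, character(1)))
    expect_true(all(diff(sevr) >= 0))
    expect_identical(sort(unique(sevr)), c(0, 1, 2, 3))
  }

  # decreasing sin(theta)/lambda never lowers the resolution level
  sintls <- seq(1.0, 0.2, by = -0.01)
  sevres <- alert_severity(vapply(sintls, function(s) {
    resolution_alert(structure(list(d = 1 / (2 * s),
                                    sin_theta_over_lambda = s,
                                    source = "computed"),
                               class = "resolution_value"), cfg)
  }, character(1)))
  expect_true(all(diff(sevres) >= 0))
})

test_that("bisection recovers every configured threshold to 1e-9", {
  bisect <- function(f, lo, hi, tol = 1e-12) {
    # f: TRUE above the boundary; returns the switch point
    for (k in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid)) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  b_r <- bisect(function(x) fit_metric_alerts(list(r = x), cfg)[["r"]] != "none",
                0.01, 1)
  expect_equal(b_r, 0.1, tolerance = 1e-9)
  b_wr <- bisect(function(x) fit_metric_alerts(list(wr = x), cfg)[["wr"]] != "none",
                 0.01, 1)
  expect_equal(b_wr, 0.25, tolerance = 1e-9)
  b_gc <- bisect(function(x) {
    fit_metric_alerts(list(goof = x), cfg)[["goof"]] != "none"
  }, 1, 3)
  expect_equal(b_gc, 2.0, tolerance = 1e-9)
  b_ga <- bisect(function(x) {
    fit_metric_alerts(list(goof = x), cfg)[["goof"]] == "A"
  }, 1, 10)
  expect_equal(b_ga, 6.0, tolerance = 1e-9)
  b_dc <- bisect(function(x) {
    residual_density_alert(x, z_max = 40, cfg = cfg) != "none"
  }, 0.1, 10)
  expect_equal(b_dc / 40, 0.075, tolerance = 1e-9)
})

test_that("evaluate_entry aggregates per-metric alerts", {
  clean <- data.frame(identifier = "ok", r = 0.05, wr = 0.12, goof = 1.0,
                      shift_su = 0.001, rho_max = 0.3, rho_min = -0.25,
                      theta_max = 28, wavelength = 0.71073,
                      resolution_reported = NA_real_, z_max = 8L)
  rep0 <- evaluate_entry(clean)
  expect_identical(rep0$overall, "none")
  expect_equal(sum(rep0$n_by_level), 0)

  two_c <- data.frame(identifier = "cc", r = 0.12, wr = NA_real_, goof = 2.5,
                      shift_su = NA_real_, rho_max = NA_real_,
                      rho_min = NA_real_, theta_max = NA_real_,
                      wavelength = NA_real_, resolution_reported = NA_real_,
                      z_max = 8L)
  rep2 <- evaluate_entry(two_c)
  expect_identical(rep2$overall, "C")
  expect_equal(unname(rep2$n_by_level[["C"]]), 2)

  # max-severity aggregation: rho_max above 2*DTEST dominates an R alert
  worst <- two_c
  worst$rho_max <- 2.1 * dtest_threshold(8)
  repw <- evaluate_entry(worst)
  expect_identical(repw$overall, "A")

  # missing z_max skips the residual-density test with a flag
  noz <- two_c
  noz$rho_max <- 5
  noz$z_max <- NA_integer_
  repz <- evaluate_entry(noz)
  expect_true("residual_density" %in% names(repz$skipped))
})

test_that("strict-goof profile tightens only the GooF bands", {
  sg <- alert_thresholds("strict-goof")
  expect_identical(fit_metric_alerts(list(goof = 2.5), sg)[["goof"]], "B")
  expect_identical(fit_metric_alerts(list(goof = 5.0), sg)[["goof"]], "A")
  expect_identical(fit_metric_alerts(list(r = 0.12), sg)[["r"]], "C")
  expect_true("goof_c" %in% sg$non_paper_defaults)
})
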