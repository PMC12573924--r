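# checkCIF-style alert levels for the audited metrics. Thresholds are strict
# ("above"/"below"): a value exactly at a boundary does not trigger.

.alert_rank <- c(none = 0, C = 1, B = 2, A = 3)

#' Severity rank of an alert level
#'
#' @param level character vector over `"A"`, `"B"`, `"C"`, `"none"`.
#' @return integer severity, `A` (3) > `B` (2) > `C` (1) > `none` (0).
#' @export
alert_severity <- function(level) {
  r <- .alert_rank[level]
  if (anyNA(r)) stop("unknown alert level: ",
                     paste(level[is.na(r)], collapse = ", "))
  unname(r)
}

#' Worst of several alert levels
#'
#' @param levels character vector of alert levels.
#' @return the single most severe level (`"none"` for empty input).
#' @export
worst_alert <- function(levels) {
  if (length(levels) == 0L) return("none")
  names(.alert_rank)[max(alert_severity(levels)) + 1L]
}

#' Alert threshold configuration
#'
#' The default profile carries the published checkCIF boundaries: R-factor
#' C alert above 0.1, wR C alert above 0.25; goodness-of-fit A outside
#' (0.4, 6.0), B outside (0.6, 4.0), C outside (0.8, 2.0); residual-density
#' DTEST multiplier 0.1 with A above twice DTEST and B/C above 10%/7.5% of
#' Zmax; resolution C alert below sin(theta)/lambda = 0.6 1/Angstrom. The
#' shift/su C threshold (default 0.2) is a package default, not a published
#' boundary, and is flagged as such in `non_paper_defaults`.
#'
#' The `"strict-goof"` profile moves the goodness-of-fit C boundary inward to
#' the published A/B-style recalibration proposal (C outside (0.8, 2.0)
#' becomes the B band and (0.6, 4.0) the A band); it is optional and never
#' the default.
#'
#' @param profile `"checkcif"` (default) or `"strict-goof"`.
#' @return named list of thresholds with attribute-free plain numbers plus a
#'   `non_paper_defaults` character vector naming flagged settings.
#' @export
alert_thresholds <- function(profile = c("checkcif", "strict-goof")) {
  profile <- match.arg(profile)
  cfg <- list(
    r_c = 0.1,
    wr_c = 0.25,
    goof_a = c(0.4, 6.0),
    goof_b = c(0.6, 4.0),
    goof_c = c(0.8, 2.0),
    dtest_multiplier = 0.1,
    dtest_a_factor = 2,
    dtest_b_fraction = 0.10,
    dtest_c_fraction = 0.075,
    resolution_sintl_min = 0.6,
    shift_c = 0.2,
    profile = profile,
    non_paper_defaults = "shift_c"
  )
  if (profile == "strict-goof") {
    cfg$goof_a <- c(0.6, 4.0)
    cfg$goof_b <- c(0.8, 2.0)
    cfg$goof_c <- c(0.9, 1.5)
    cfg$non_paper_defaults <- c("shift_c", "goof_c")
  }
  cfg
}

#' Residual-density alert level
#'
#' Evaluates `rho = max(rho_max, |rho_min|)` against the DTEST scheme:
#' level A above twice DTEST (i.e. 20% of Zmax), B above 10% of Zmax, C above
#' 7.5% of Zmax, strictly.
#'
#' @param rho_max maximum residual density, e/A^3 (`NA` allowed).
#' @param rho_min minimum residual density, e/A^3 (`NA` allowed).
#' @param z_max largest atomic number in the structure.
#' @param cfg see [alert_thresholds()].
#' @return alert level string.
#' @export
residual_density_alert <- function(rho_max, rho_min = NA_real_, z_max,
                                   cfg = alert_thresholds()) {
  if (is.na(z_max) || z_max < 1) {
    stop("residual-density alert requires z_max >= 1")
  }
  rho <- suppressWarnings(
    max(c(rho_max, absolute_min_density(rho_min)), na.rm = TRUE))
  if (!is.finite(rho)) return("none")
  dtest <- dtest_threshold(z_max, cfg$dtest_multiplier)
  if (rho > cfg$dtest_a_factor * dtest) return("A")
  if (rho > cfg$dtest_b_fraction * z_max) return("B")
  if (rho > cfg$dtest_c_fraction * z_max) return("C")
  "none"
}

# Two-sided band alert: triggers when x falls strictly outside (lo, hi).
.outside <- function(x, band) x < band[1] || x > band[2]

#' Fit-metric alerts (R, wR, goodness of fit, shift/su)
#'
#' R and wR carry only a level C boundary (above 0.1 and 0.25 respectively;
#' no A/B levels exist for them). Goodness of fit escalates through nested
#' two-sided bands: A outside (0.4, 6.0), else B outside (0.6, 4.0), else C
#' outside (0.8, 2.0). Shift/su gets a C alert above the configured
#' `shift_c` (a flagged non-published default).
#'
#' @param record one curated record row (list or data.frame row with `r`,
#'   `wr`, `goof`, `shift_su`; `NA` metrics produce no alert).
#' @param cfg see [alert_thresholds()].
#' @return named character vector of levels for `r`, `wr`, `goof`,
#'   `shift_su`.
#' @export
fit_metric_alerts <- function(record, cfg = alert_thresholds()) {
  lv <- c(r = "none", wr = "none", goof = "none", shift_su = "none")
  r <- record$r
  if (!is.null(r) && !is.na(r) && r > cfg$r_c) lv[["r"]] <- "C"
  wr <- record$wr
  if (!is.null(wr) && !is.na(wr) && wr > cfg$wr_c) lv[["wr"]] <- "C"
  g <- record$goof
  if (!is.null(g) && !is.na(g)) {
    if (.outside(g, cfg$goof_a)) {
      lv[["goof"]] <- "A"
    } else if (.outside(g, cfg$goof_b)) {
      lv[["goof"]] <- "B"
    } else if (.outside(g, cfg$goof_c)) {
      lv[["goof"]] <- "C"
    }
  }
  s <- record$shift_su
  if (!is.null(s) && !is.na(s) && s > cfg$shift_c) lv[["shift_su"]] <- "C"
  lv
}

#' Resolution alert level
#'
#' C alert iff `sin(theta)/lambda` is strictly below the configured minimum
#' (0.6 1/Angstrom by default).
#'
#' @param res a `resolution_value` (see [resolution_from_bragg()]).
#' @param cfg see [alert_thresholds()].
#' @return alert level string.
#' @export
resolution_alert <- function(res, cfg = alert_thresholds()) {
  stopifnot(inherits(res, "resolution_value"))
  if (res$sin_theta_over_lambda < cfg$resolution_sintl_min) "C" else "none"
}

#' Evaluate all alerts for one entry
#'
#' Aggregates the fit-metric, residual-density and resolution alerts; absent
#' metrics produce no alert, and a missing Zmax skips the residual-density
#' test with a flag rather than erroring.
#'
#' @param record one curated record row (needs the metric columns plus
#'   `z_max`, `wavelength`, `theta_max`, optionally `resolution_reported`).
#' @param labels optional `category_labels` (carried through to the report).
#' @param cfg see [alert_thresholds()].
#' @return list of class `alert_report`: `levels` (named per-metric vector),
#'   `overall`, `n_by_level`, `skipped` (named reasons), `values`.
#' @export
evaluate_entry <- function(record, labels = NULL, cfg = alert_thresholds()) {
  levels <- fit_metric_alerts(record, cfg)
  skipped <- character(0)

  zm <- record$z_max
  has_rho <- (!is.null(record$rho_max) && !is.na(record$rho_max)) ||
    (!is.null(record$rho_min) && !is.na(record$rho_min))
  if (has_rho) {
    if (is.null(zm) || is.na(zm)) {
      skipped <- c(skipped, residual_density = "z_max unavailable")
    } else {
      levels[["residual_density"]] <- residual_density_alert(
        record$rho_max, record$rho_min, zm, cfg)
    }
  }

  res <- resolution_for_record(record)
  if (!is.null(res)) {
    levels[["resolution"]] <- resolution_alert(res, cfg)
  }

  sev <- alert_severity(levels)
  structure(
    list(identifier = record$identifier %||% NA_character_,
         levels = levels,
         overall = worst_alert(levels),
         n_by_level = c(A = sum(sev == 3), B = sum(sev == 2),
                        C = sum(sev == 1)),
         skipped = skipped,
         labels = labels),
    class = "alert_report"
  )
}

#' @export
print.alert_report <- function(x, ...) {
  cat(sprintf("<alert_report> %s: overall %s (A=%d B=%d C=%d)\n",
              x$identifier, x$overall,
              x$n_by_level[["A"]], x$n_by_level[["B"]], x$n_by_level[["C"]]))
  trig <- x$levels[x$levels != "none"]
  for (m in names(trig)) cat(sprintf("  %-16s %s\n", m, trig[[m]]))
  invisible(x)
}
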