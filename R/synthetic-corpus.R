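# Seeded synthetic CIF corpus generator.
#
# The generator emulates the statistical structure of an archive-scale
# quality-metric survey: skewed marginals anchored to published central
# values, a bimodal theta_max tied to the radiation wavelength, Zmax-coupled
# residual densities, a multiplicative wR/R link, category mixtures, and
# quota-exact injection of missing / malformed / out-of-range values with a
# ground-truth table. All marginals are truncated inside the validity ranges
# before injection so the "valid population" and the "contamination" are
# cleanly separated.

# Anchors for the default stated world (central values of the emulated
# survey distributions and per-item completeness/contamination rates).
.default_anchors <- list(
  r_median = 0.046, r_mean = 0.054,
  wr_median = 0.118,
  goof_median = 1.045, goof_p10 = 0.969, goof_p90 = 1.143,
  shift_median = 0.001,
  rho_max_median = 0.596, rho_min_abs_median = 0.481,
  completeness = c(r = 0.957, wr = 0.944, shift_su = 0.942,
                   rho_max = 0.973, rho_min = 0.973, goof = 0.944,
                   theta_max = 0.973),
  # share of the incompleteness that is malformed text rather than absence;
  # the shift item carries the bulk of the "<0.01"-style bounded values
  malformed_rate = c(r = 0.002, wr = 0.002, shift_su = 0.017,
                     rho_max = 0.0004, rho_min = 0.0004, goof = 0.002,
                     theta_max = 0.002),
  # out-of-range counts per archive file, scaled to corpus size
  oor_rate = c(r = 279, wr = 19, shift_su = 1781, rho_max = 508,
               rho_min = 566, goof = 27, theta_max = 66) / 1086480,
  wavelength_missing_rate = 0.02
)

# Mixture CDF of the rho_max population at value x given Zmax weights.
.rho_mix_cdf <- function(x, scale, gamma, sdlog, z, w) {
  ml <- log(scale) + gamma * log(z / 8)
  sum(w * stats::plnorm(x, meanlog = ml, sdlog = sdlog))
}

# Population CDF of |rho_min| = rho_max * Beta(shape1, shape2).
.rho_min_cdf <- function(x, scale, gamma, sdlog, z, w, shape1, shape2) {
  stats::integrate(function(f) {
    vapply(f, function(fi) {
      .rho_mix_cdf(x / fi, scale, gamma, sdlog, z, w) *
        stats::dbeta(fi, shape1, shape2)
    }, numeric(1))
  }, lower = 1e-9, upper = 1 - 1e-9, rel.tol = 1e-9)$value
}

#' Build the default synthetic corpus specification
#'
#' Calibrates every marginal to the survey anchors: R lognormal with
#' population median 0.046 and mean 0.054 (`sdlog^2 = 2 log(mean/median)`),
#' wR as R times a lognormal factor with median 0.118/0.046 (truncated above
#' 1 so wR > R always holds), goodness of fit as 0.8 plus a lognormal with
#' median 1.045 and 90th percentile 1.143, shift/su as a zero-inflated
#' exponential with median 0.001, theta_max as a wavelength-tied mixture
#' (Mo radiation near 26 degrees, Cu near 68), and rho_max as a
#' Zmax-coupled lognormal whose mixture median is calibrated numerically to
#' 0.596, with rho_min = -rho_max times a beta factor whose shape is
#' calibrated so the population median of |rho_min| is 0.481. Injection
#' quotas (exact counts, not Bernoulli rates) reproduce the per-item
#' completeness and non-permitted-value rates of the emulated survey.
#'
#' @param n number of entries (default 20000).
#' @param seed RNG seed stored in the spec.
#' @return list of class `corpus_spec`.
#' @export
build_default_spec <- function(n = 20000, seed = 1L) {
  a <- .default_anchors
  sdlog_r <- sqrt(2 * log(a$r_mean / a$r_median))
  goof_sdlog <- log((a$goof_p90 - 0.8) / (a$goof_median - 0.8)) /
    stats::qnorm(0.9)
  shift_zero_fraction <- 0.3
  shift_rate <- -log(1 - (0.5 - shift_zero_fraction) /
                       (1 - shift_zero_fraction)) / a$shift_median

  palette_organic <- c(O = 0.40, S = 0.25, Cl = 0.20, Br = 0.10, I = 0.05)
  palette_metal <- c(Fe = 0.18, Cu = 0.15, Zn = 0.12, Ru = 0.10, Pd = 0.10,
                     Sn = 0.08, Pt = 0.10, Pb = 0.07, Bi = 0.05, U = 0.05)
  organic_fraction <- 0.450
  zsyms <- c(names(palette_organic), names(palette_metal))
  zvals <- element_z(zsyms)
  zw <- c(organic_fraction * palette_organic,
          (1 - organic_fraction) * palette_metal)

  rho_sdlog <- 0.75
  rho_gamma <- 0.7
  rho_scale <- stats::uniroot(function(s) {
    .rho_mix_cdf(a$rho_max_median, s, rho_gamma, rho_sdlog, zvals, zw) - 0.5
  }, interval = c(0.02, 1.0), tol = 1e-10)$root
  rho_min_shape1 <- 8
  rho_min_shape2 <- stats::uniroot(function(b) {
    .rho_min_cdf(a$rho_min_abs_median, rho_scale, rho_gamma, rho_sdlog,
                 zvals, zw, rho_min_shape1, b) - 0.5
  }, interval = c(1.05, 10), tol = 1e-8)$root

  tags <- c("r", "wr", "shift_su", "rho_max", "rho_min", "goof", "theta_max")
  missing_rate <- 1 - a$completeness[tags] - a$malformed_rate[tags]
  quotas <- data.frame(
    metric = tags,
    missing = as.integer(round(missing_rate * n)),
    malformed = as.integer(round(a$malformed_rate[tags] * n)),
    out_of_range = as.integer(round(a$oor_rate[tags] * n)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  structure(list(
    n = as.integer(n),
    seed = as.integer(seed),
    category = list(
      organic_fraction = organic_fraction,
      disordered_fraction = 0.312,
      squeeze_fraction = 0.15,     # of disordered entries, flagged via text
      polymeric_fraction = 0.130,
      aspherical_fraction = 0.0017,
      high_pressure_fraction = 0.0043,
      radiation = c(xray = 0.99894, neutron = 0.00068, electron = 0.00038),
      mo_fraction = 0.62           # within X-ray: Mo vs Cu tube
    ),
    wavelengths = c(mo = 0.71073, cu = 1.54184, neutron = 1.30,
                    electron = 0.0251),
    theta = list(mo = c(mean = 26, sd = 2.5), cu = c(mean = 68, sd = 4),
                 neutron = c(mean = 45, sd = 8),
                 electron = c(mean = 0.8, sd = 0.1)),
    marginals = list(
      r = list(meanlog = log(a$r_median), sdlog = sdlog_r, upper = 0.995),
      wr_factor = list(meanlog = log(a$wr_median / a$r_median), sdlog = 0.30,
                       min_gap = 1.5e-4, upper_frac = 0.999),
      goof = list(offset = 0.8, meanlog = log(a$goof_median - 0.8),
                  sdlog = goof_sdlog, upper = 19.0),
      shift = list(zero_fraction = shift_zero_fraction, tiny_lo = 1e-6,
                   tiny_hi = 1e-4, rate = shift_rate, upper = 14.9),
      rho = list(scale = rho_scale, gamma = rho_gamma, sdlog = rho_sdlog,
                 upper = 117.5),
      rho_min_factor = list(shape1 = rho_min_shape1, shape2 = rho_min_shape2)
    ),
    palette = list(organic = palette_organic, metal = palette_metal),
    quotas = quotas,
    wavelength_missing = as.integer(round(a$wavelength_missing_rate * n)),
    anchors = a
  ), class = "corpus_spec")
}

#' @export
print.corpus_spec <- function(x, ...) {
  cat(sprintf("<corpus_spec> n=%d seed=%d\n", x$n, x$seed))
  cat(sprintf("  R median %.3f | GooF median %.3f | rho_max median %.3f\n",
              exp(x$marginals$r$meanlog),
              x$marginals$goof$offset + exp(x$marginals$goof$meanlog),
              x$anchors$rho_max_median))
  invisible(x)
}

# Inverse-CDF draw from a normal truncated to (lo, hi).
.rtruncnorm <- function(u, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

# Deterministic categorical draw from uniforms.
.draw_categorical <- function(u, weights) {
  br <- cumsum(weights) / sum(weights)
  names(weights)[findInterval(u, c(0, br), rightmost.closed = TRUE)]
}

# Malformed-value templates, cycled deterministically by injection index.
.malformed_templates <- list(
  shift_su = c("<0.01", "<0.001", "<0.01", "<0.0001", "not_determined"),
  default = c("n/a", "see_text", "1.0a", "ca. 0.05")
)

# Out-of-range replacement values per metric, strictly outside the default
# validity intervals; index parity alternates the violation side.
.oor_value <- function(metric, k, u) {
  even <- k %% 2L == 0L
  switch(metric,
    r = if (even) sprintf("%.4f", -u) else sprintf("%.3f", 1.5 + 50 * u),
    wr = if (even) sprintf("%.4f", -u) else sprintf("%.3f", 1.5 + 30 * u),
    shift_su = sprintf("%.1f", 16 + 4000 * u),
    rho_max = sprintf("%.1f", 120 + 800 * u),
    rho_min = if (even) sprintf("%.1f", -(119 + 300 * u))
              else sprintf("%.3f", 0.2 + 4 * u),
    goof = sprintf("%.2f", 21 + 60 * u),
    theta_max = sprintf("%.2f", 91 + 260 * u)
  )
}

.metric_tag <- c(
  r = "_refine_ls_R_factor_gt",
  wr = "_refine_ls_wR_factor_ref",
  shift_su = "_refine_ls_shift/su_max",
  rho_max = "_refine_diff_density_max",
  rho_min = "_refine_diff_density_min",
  goof = "_refine_ls_goodness_of_fit_ref",
  theta_max = "_diffrn_reflns_theta_max"
)

.metric_fmt <- c(r = "%.4f", wr = "%.4f", shift_su = "%.6f",
                 rho_max = "%.4f", rho_min = "%.4f", goof = "%.3f",
                 theta_max = "%.4f")

#' Generate a synthetic CIF corpus
#'
#' Writes exactly `spec$n` syntactically valid CIF 1.1 files plus a
#' ground-truth table (`ground_truth.csv`) to `dir`. Injections (missing,
#' malformed, out-of-range) are applied by exact quota at seeded-random,
#' mutually disjoint positions per item. Output is byte-identical for
#' identical `(spec, seed)`.
#'
#' @param spec a `corpus_spec` (see [build_default_spec()]).
#' @param dir writable output directory (created if needed).
#' @return list with `dir`, `files` (paths in entry order), `ground_truth`
#'   (data.frame; also written as CSV), invisibly.
#' @export
generate_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create output directory: ", dir)
  }
  n <- spec$n
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")

  cat_ <- spec$category
  # --- category draws (fixed order for determinism) ---
  chem <- ifelse(stats::runif(n) < cat_$organic_fraction,
                 "organic", "metal_organic")
  u_z <- stats::runif(n)
  zsym <- character(n)
  org <- chem == "organic"
  zsym[org] <- .draw_categorical(u_z[org], spec$palette$organic)
  zsym[!org] <- .draw_categorical(u_z[!org], spec$palette$metal)
  z <- element_z(zsym)

  disordered <- stats::runif(n) < cat_$disordered_fraction
  squeeze_mode <- stats::runif(n) < cat_$squeeze_fraction
  polymeric <- stats::runif(n) < cat_$polymeric_fraction
  aspherical <- stats::runif(n) < cat_$aspherical_fraction
  high_pressure <- stats::runif(n) < cat_$high_pressure_fraction
  pressure_written <- stats::runif(n) < 0.1   # ambient entries sometimes report
  pressure_kpa <- stats::runif(n, 5e5, 1e7)   # used only when high pressure

  radiation <- .draw_categorical(stats::runif(n), cat_$radiation)
  mo_tube <- stats::runif(n) < cat_$mo_fraction
  tube <- ifelse(radiation == "xray", ifelse(mo_tube, "mo", "cu"), radiation)
  wavelength <- spec$wavelengths[tube]

  u_th <- stats::runif(n)
  theta <- numeric(n)
  for (t in c("mo", "cu", "neutron", "electron")) {
    i <- tube == t
    if (any(i)) {
      p <- spec$theta[[t]]
      theta[i] <- .rtruncnorm(u_th[i], p[["mean"]], p[["sd"]], 0.01, 89.9)
    }
  }

  # --- metric draws ---
  mg <- spec$marginals
  u_r <- stats::runif(n)
  r <- stats::qlnorm(u_r * stats::plnorm(mg$r$upper, mg$r$meanlog,
                                         mg$r$sdlog),
                     mg$r$meanlog, mg$r$sdlog)
  f_lo <- 1 + mg$wr_factor$min_gap / r
  f_hi <- mg$wr_factor$upper_frac / r
  u_f <- stats::runif(n)
  p_lo <- stats::plnorm(f_lo, mg$wr_factor$meanlog, mg$wr_factor$sdlog)
  p_hi <- stats::plnorm(f_hi, mg$wr_factor$meanlog, mg$wr_factor$sdlog)
  wr <- r * stats::qlnorm(p_lo + u_f * (p_hi - p_lo),
                          mg$wr_factor$meanlog, mg$wr_factor$sdlog)

  u_g <- stats::runif(n)
  goof <- mg$goof$offset +
    stats::qlnorm(u_g * stats::plnorm(mg$goof$upper, mg$goof$meanlog,
                                      mg$goof$sdlog),
                  mg$goof$meanlog, mg$goof$sdlog)

  u_sz <- stats::runif(n)
  u_tiny <- stats::runif(n)
  u_exp <- stats::runif(n)
  shift <- ifelse(
    u_sz < mg$shift$zero_fraction,
    mg$shift$tiny_lo + u_tiny * (mg$shift$tiny_hi - mg$shift$tiny_lo),
    stats::qexp(u_exp * stats::pexp(mg$shift$upper, mg$shift$rate),
                mg$shift$rate))
  shift <- pmax(shift, mg$shift$tiny_lo)  # keep above zero at fixed precision

  ml_z <- log(mg$rho$scale) + mg$rho$gamma * log(z / 8)
  u_rho <- stats::runif(n)
  rho_max <- stats::qlnorm(
    u_rho * stats::plnorm(mg$rho$upper, ml_z, mg$rho$sdlog),
    ml_z, mg$rho$sdlog)
  rho_max <- pmax(rho_max, 1e-3)  # degenerate-draw guard for fixed formatting
  f_beta <- stats::rbeta(n, mg$rho_min_factor$shape1,
                         mg$rho_min_factor$shape2)
  rho_min <- -pmax(rho_max * f_beta, 1e-3)

  n_parameters <- sample(60:900, n, replace = TRUE)
  n_restraints <- stats::rpois(n, ifelse(disordered, 12, 1))
  n_constraints <- stats::rpois(n, 0.3)
  occ_partial <- stats::runif(n, 0.2, 0.8)

  # format exactly as written so ground truth matches the parsed corpus
  true_vals <- data.frame(
    r = as.numeric(sprintf(.metric_fmt[["r"]], r)),
    wr = as.numeric(sprintf(.metric_fmt[["wr"]], wr)),
    shift_su = as.numeric(sprintf(.metric_fmt[["shift_su"]], shift)),
    rho_max = as.numeric(sprintf(.metric_fmt[["rho_max"]], rho_max)),
    rho_min = as.numeric(sprintf(.metric_fmt[["rho_min"]], rho_min)),
    goof = as.numeric(sprintf(.metric_fmt[["goof"]], goof)),
    theta_max = as.numeric(sprintf(.metric_fmt[["theta_max"]], theta))
  )

  # --- quota-exact injections at seeded disjoint positions ---
  texts <- lapply(names(.metric_tag), function(mcol) {
    sprintf(.metric_fmt[[mcol]], true_vals[[mcol]])
  })
  names(texts) <- names(.metric_tag)
  inject <- lapply(names(.metric_tag), function(mcol) rep("none", n))
  names(inject) <- names(.metric_tag)

  for (mcol in spec$quotas$metric) {
    qr <- spec$quotas[spec$quotas$metric == mcol, ]
    total <- qr$missing + qr$malformed + qr$out_of_range
    if (total == 0L) next
    idx <- sample.int(n, total)
    i_mis <- idx[seq_len(qr$missing)]
    i_mal <- idx[qr$missing + seq_len(qr$malformed)]
    i_oor <- idx[qr$missing + qr$malformed + seq_len(qr$out_of_range)]
    texts[[mcol]][i_mis] <- "?"
    inject[[mcol]][i_mis] <- "missing"
    if (qr$malformed > 0L) {
      tpl <- .malformed_templates[[mcol]]
      if (is.null(tpl)) tpl <- .malformed_templates$default
      texts[[mcol]][i_mal] <- tpl[((seq_len(qr$malformed) - 1L) %% length(tpl)) + 1L]
      inject[[mcol]][i_mal] <- "malformed"
    }
    if (qr$out_of_range > 0L) {
      u_oor <- stats::runif(qr$out_of_range)
      texts[[mcol]][i_oor] <- vapply(seq_len(qr$out_of_range), function(k) {
        .oor_value(mcol, k, u_oor[k])
      }, character(1))
      inject[[mcol]][i_oor] <- "out_of_range"
    }
  }

  wl_text <- sprintf("%.5f", wavelength)
  wl_missing <- rep(FALSE, n)
  if (spec$wavelength_missing > 0L) {
    i_wl <- sample.int(n, spec$wavelength_missing)
    wl_text[i_wl] <- "?"
    wl_missing[i_wl] <- TRUE
  }

  # --- write files ---
  ids <- sprintf("SYN%06d", seq_len(n))
  files <- file.path(dir, paste0(ids, ".cif"))
  base_elements <- c("C", "H", "N", "O")
  for (i in seq_len(n)) {
    lines <- c(
      paste0("data_", ids[i]),
      "_audit_creation_method 'cifaudit synthetic corpus'"
    )
    if (radiation[i] != "xray") {
      lines <- c(lines, paste("_diffrn_radiation_probe", radiation[i]))
    }
    lines <- c(lines,
      paste("_diffrn_radiation_wavelength", wl_text[i]),
      paste("_diffrn_reflns_theta_max", texts$theta_max[i]),
      paste("_refine_ls_R_factor_gt", texts$r[i]),
      paste("_refine_ls_wR_factor_ref", texts$wr[i]),
      paste("_refine_ls_goodness_of_fit_ref", texts$goof[i]),
      paste("_refine_ls_shift/su_max", texts$shift_su[i]),
      paste("_refine_diff_density_max", texts$rho_max[i]),
      paste("_refine_diff_density_min", texts$rho_min[i]),
      paste("_refine_ls_number_parameters", n_parameters[i]),
      paste("_refine_ls_number_restraints", n_restraints[i]),
      paste("_refine_ls_number_constraints", n_constraints[i])
    )
    if (high_pressure[i]) {
      lines <- c(lines, paste("_diffrn_ambient_pressure",
                              sprintf("%.1f", pressure_kpa[i])))
    } else if (pressure_written[i]) {
      lines <- c(lines, "_diffrn_ambient_pressure 101.3")
    }
    details <- character(0)
    if (disordered[i] && squeeze_mode[i]) {
      details <- c(details, "SQUEEZE used to treat unmodelled solvent density.")
    }
    if (aspherical[i]) {
      details <- c(details, "Aspherical multipole refinement.")
    }
    if (length(details)) {
      lines <- c(lines, paste0("_refine_special_details '",
                               paste(details, collapse = " "), "'"))
    }
    elems <- unique(c(base_elements, zsym[i]))
    lines <- c(lines, "loop_", " _atom_site_label", " _atom_site_type_symbol",
               " _atom_site_occupancy", " _atom_site_disorder_group")
    site_lines <- paste0(elems, "1 ", elems, " 1 .")
    if (disordered[i] && !squeeze_mode[i]) {
      site_lines <- c(site_lines,
                      sprintf("C9A C %.3f 1", occ_partial[i]))
    }
    lines <- c(lines, site_lines)
    writeLines(lines, files[i])
  }

  ground_truth <- data.frame(
    identifier = ids,
    chemistry = chem,
    disordered = disordered,
    radiation = radiation,
    polymeric = polymeric,
    refinement_type = ifelse(aspherical, "aspherical", "independent_atom"),
    pressure = ifelse(high_pressure, "non_ambient", "ambient"),
    z_max_symbol = zsym,
    z_max = z,
    wavelength = ifelse(wl_missing, NA_real_, round(wavelength, 5)),
    true_vals,
    stringsAsFactors = FALSE
  )
  for (mcol in names(inject)) {
    ground_truth[[paste0("inj_", mcol)]] <- inject[[mcol]]
  }
  utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(list(dir = dir, files = files, ground_truth = ground_truth,
                 spec = spec))
}
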