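# Independent oracles and fixture builders shared across the suite.
# Oracles are deliberately naive (sorting, counting, closed forms) and never
# call the implementation paths they check.

# Sort-based type-7 quantile: linear interpolation between order statistics.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Brute-force mid-rank percentile by counting.
oracle_percentile <- function(value, cohort) {
  below <- 0
  equal <- 0
  for (v in cohort) {
    if (v < value) below <- below + 1
    if (v == value) equal <- equal + 1
  }
  100 * (below + equal / 2) / length(cohort)
}

# Two-pass sample variance (n-1 denominator).
oracle_variance <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

# Relativistic electron wavelength (Angstrom) at accelerating voltage V_kv.
# lambda = h / sqrt(2 m e V (1 + e V / (2 m c^2)))
electron_wavelength <- function(v_kv) {
  h <- 6.62607015e-34
  me <- 9.1093837015e-31
  e <- 1.602176634e-19
  c <- 299792458
  V <- v_kv * 1e3
  1e10 * h / sqrt(2 * me * e * V * (1 + e * V / (2 * me * c^2)))
}

# Write CIF text lines to a temp file and return the path.
write_cif_text <- function(lines) {
  path <- tempfile("fixture", fileext = ".cif")
  writeLines(lines, path)
  path
}

# A minimal complete entry with controllable item values.
fixture_cif_lines <- function(id = "test",
                              r = "0.0460", wr = "0.1180", goof = "1.045",
                              shift = "0.001", rho_max = "0.596",
                              rho_min = "-0.481", theta = "26.37",
                              wavelength = "0.71073",
                              extra = character(0),
                              atoms = c("C1 C 1 .", "H1 H 1 .",
                                        "N1 N 1 .", "O1 O 1 .")) {
  item <- function(tag, v) if (is.null(v)) character(0) else paste(tag, v)
  c(paste0("data_", id),
    item("_refine_ls_R_factor_gt", r),
    item("_refine_ls_wR_factor_ref", wr),
    item("_refine_ls_goodness_of_fit_ref", goof),
    item("_refine_ls_shift/su_max", shift),
    item("_refine_diff_density_max", rho_max),
    item("_refine_diff_density_min", rho_min),
    item("_diffrn_reflns_theta_max", theta),
    item("_diffrn_radiation_wavelength", wavelength),
    extra,
    if (length(atoms)) {
      c("loop_", " _atom_site_label", " _atom_site_type_symbol",
        " _atom_site_occupancy", " _atom_site_disorder_group", atoms)
    })
}

# Build raw item sets directly (bypassing file I/O) for curation tests.
raw_set <- function(id, ...) {
  vals <- c(...)
  tags <- survey_tags("survey")
  out <- rep(NA_character_, length(tags))
  names(out) <- tags
  out[names(vals)] <- vals
  structure(out, identifier = id, class = "raw_item_set")
}

# Shared small synthetic corpus, generated once per test run.
shared_corpus <- local({
  cache <- NULL
  function(n = 400, seed = 11) {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), sprintf("cifaudit-shared-%d-%d", n, seed))
      spec <- build_default_spec(n = n, seed = seed)
      gen <- generate_corpus(spec, dir)
      entries <- unlist(lapply(gen$files, read_cif_blocks), recursive = FALSE)
      cache <<- list(spec = spec, gen = gen, entries = entries,
                     audit = audit_cif_entries(entries))
    }
    cache
  }
})
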