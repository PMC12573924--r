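# Curation: raw item text -> {numeric, bounded, missing, malformed},
# validity-range filtering and corpus completeness accounting.

# Canonical mapping tag -> record column name.
.tag_columns <- c(
  "_refine_ls_r_factor_gt" = "r",
  "_refine_ls_wr_factor_ref" = "wr",
  "_refine_ls_shift/su_max" = "shift_su",
  "_refine_diff_density_max" = "rho_max",
  "_refine_diff_density_min" = "rho_min",
  "_refine_ls_goodness_of_fit_ref" = "goof",
  "_diffrn_reflns_theta_max" = "theta_max"
)

#' Parse one raw CIF value
#'
#' Applies the CIF conventions: `"?"`, `"."` and absence mean *missing*; a
#' number with a parenthesized suffix is numeric with a standard uncertainty
#' applied to the last digit(s) (`"0.71073(10)"` has su 0.00010); a leading
#' `<` or `>` marks a *bounded* value (kept verbatim in `bound_text`);
#' anything else non-numeric -- including trailing junk after a number -- is
#' *malformed*. Every input is classified; nothing errors.
#'
#' @param raw a single raw value string, or `NA` for absence.
#' @return a `parsed_value`: list with `status` (one of `"numeric"`,
#'   `"bounded"`, `"missing"`, `"malformed"`), `value` (finite numeric, only
#'   when numeric), `su` (numeric or `NA`), `bound_text`.
#' @export
parse_value <- function(raw) {
  pv <- function(status, value = NA_real_, su = NA_real_,
                 bound_text = NA_character_) {
    structure(list(status = status, value = value, su = su,
                   bound_text = bound_text), class = "parsed_value")
  }
  if (length(raw) != 1L || is.na(raw)) return(pv("missing"))
  raw <- as.character(raw)
  if (raw %in% c("?", ".")) return(pv("missing"))
  if (grepl("^[<>]", raw)) return(pv("bounded", bound_text = raw))
  num_re <- "^([+-]?)([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?(\\(([0-9]+)\\))?$"
  m <- regmatches(raw, regexec(num_re, raw))[[1]]
  if (length(m) == 0L) return(pv("malformed"))
  base <- paste0(m[2], m[3], m[4])
  value <- suppressWarnings(as.numeric(base))
  if (is.na(value) || !is.finite(value)) return(pv("malformed"))
  su <- NA_real_
  if (nzchar(m[6])) {
    mantissa <- m[3]
    dec <- if (grepl(".", mantissa, fixed = TRUE)) {
      nchar(sub("^[^.]*\\.", "", mantissa))
    } else 0L
    expo <- if (nzchar(m[4])) as.numeric(sub("^[eE]", "", m[4])) else 0
    su <- as.numeric(m[6]) * 10^(expo - dec)
  }
  pv("numeric", value = value, su = su)
}

#' Default validity rules for the seven audited items
#'
#' Open intervals used to exclude impossible values: R and wR in (0, 1),
#' shift/su in (0, 15), maximum residual density in (0, 118), minimum residual
#' density in (-118, 0), goodness of fit in (0, 20), theta_max in (0, 90)
#' degrees. Bounds are strict at both ends, including zero.
#'
#' @return data.frame with columns `tag`, `lower`, `upper`.
#' @export
default_validity_rules <- function() {
  data.frame(
    tag = .survey_item_tags,
    lower = c(0, 0, 0, 0, -118, 0, 0),
    upper = c(1, 1, 15, 118, 0, 20, 90),
    stringsAsFactors = FALSE
  )
}

#' Read a validity-rule table from a CSV config file
#'
#' @param path CSV with columns `tag`, `lower`, `upper`.
#' @return data.frame usable wherever `default_validity_rules()` is.
#' @export
read_validity_rules <- function(path) {
  rules <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("tag", "lower", "upper") %in% names(rules)),
            all(rules$lower < rules$upper))
  rules$tag <- tolower(rules$tag)
  rules
}

#' Apply a validity rule to a parsed value
#'
#' Accepted iff the value is numeric and lies strictly inside the rule's open
#' interval. Bounded values ("<0.01"-style) are rejected as unreadable;
#' boundary hits (e.g. an R factor of exactly 1.0) are rejected as
#' out-of-range.
#'
#' @param tag canonical item tag (must have a rule).
#' @param pv a `parsed_value`.
#' @param rules rule table, by default [default_validity_rules()].
#' @return list with `accepted` (logical) and `reason` (`NA` when accepted,
#'   else one of `"missing"`, `"malformed"`, `"bounded-unreadable"`,
#'   `"out-of-range"`).
#' @export
apply_validity <- function(tag, pv, rules = default_validity_rules()) {
  stopifnot(inherits(pv, "parsed_value"))
  tag <- tolower(tag)
  i <- match(tag, rules$tag)
  if (is.na(i)) stop("no validity rule configured for tag ", tag)
  out <- switch(pv$status,
    missing = list(accepted = FALSE, reason = "missing"),
    malformed = list(accepted = FALSE, reason = "malformed"),
    bounded = list(accepted = FALSE, reason = "bounded-unreadable"),
    numeric = {
      if (pv$value > rules$lower[i] && pv$value < rules$upper[i]) {
        list(accepted = TRUE, reason = NA_character_)
      } else {
        list(accepted = FALSE, reason = "out-of-range")
      }
    }
  )
  out
}

#' Audit a corpus of raw item sets
#'
#' Parses and curates every requested survey item of every entry, producing
#' per-tag corpus tallies (the completeness accounting) and one metric record
#' per entry. The accounting identity `numeric + missing + non_numeric =
#' total` holds per tag, with `non_numeric = malformed + bounded` and
#' `accepted = numeric - out_of_range`.
#'
#' @param raw_sets list of `raw_item_set` objects (see [extract_items()]).
#' @param rules validity rule table.
#' @return list of class `curation_result` with `tallies` (one row per tag:
#'   total, n_numeric, n_missing, n_non_numeric, n_out_of_range, n_accepted,
#'   completeness_pct), `records` (one row per entry; metric columns are `NA`
#'   unless accepted) and `reasons` (per entry x tag rejection reason).
#' @export
audit_corpus <- function(raw_sets, rules = default_validity_rules()) {
  stopifnot(length(raw_sets) >= 1L)
  tags <- .survey_item_tags
  cols <- .tag_columns[tags]
  n <- length(raw_sets)
  ids <- vapply(raw_sets, function(s) {
    id <- attr(s, "identifier")
    if (is.null(id)) NA_character_ else id
  }, character(1))

  values <- matrix(NA_real_, nrow = n, ncol = length(tags),
                   dimnames = list(NULL, cols))
  reasons <- matrix(NA_character_, nrow = n, ncol = length(tags),
                    dimnames = list(NULL, cols))
  status <- matrix(NA_character_, nrow = n, ncol = length(tags))

  for (j in seq_along(tags)) {
    for (i in seq_len(n)) {
      raw <- unname(raw_sets[[i]][tags[j]][1])
      pv <- parse_value(raw)
      status[i, j] <- pv$status
      v <- apply_validity(tags[j], pv, rules)
      if (v$accepted) {
        values[i, j] <- pv$value
      } else {
        reasons[i, j] <- v$reason
      }
    }
  }

  n_numeric <- colSums(status == "numeric")
  n_missing <- colSums(status == "missing")
  n_non_numeric <- colSums(status == "malformed" | status == "bounded")
  n_oor <- colSums(reasons == "out-of-range", na.rm = TRUE)
  tallies <- data.frame(
    tag = tags,
    total = n,
    n_numeric = n_numeric,
    n_missing = n_missing,
    n_non_numeric = n_non_numeric,
    n_out_of_range = n_oor,
    n_accepted = n_numeric - n_oor,
    completeness_pct = 100 * n_numeric / n,
    lower = rules$lower[match(tags, rules$tag)],
    upper = rules$upper[match(tags, rules$tag)],
    row.names = NULL, stringsAsFactors = FALSE
  )

  records <- data.frame(identifier = ids, values, stringsAsFactors = FALSE)
  structure(list(tallies = tallies, records = records,
                 reasons = as.data.frame(reasons, stringsAsFactors = FALSE)),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat(sprintf("<curation_result> %d entries\n", nrow(x$records)))
  print(x$tallies[, c("tag", "total", "n_accepted", "n_missing",
                      "n_non_numeric", "n_out_of_range", "completeness_pct")],
        row.names = FALSE)
  invisible(x)
}

# Parse a value leniently (no validity rule): numeric value or NA.
.parse_numeric_or_na <- function(raw) {
  pv <- parse_value(raw)
  if (pv$status == "numeric") pv$value else NA_real_
}

#' Audit parsed CIF entries into full metric records
#'
#' Convenience wrapper around [extract_items()] and [audit_corpus()] that also
#' captures the supporting items a bare raw-item audit cannot: wavelength
#' (first-listed when looped), reported resolution, refinement counts and the
#' largest atomic number Zmax derived from the atom-site element set.
#'
#' @param entries list of `cif_entry` objects.
#' @param rules validity rule table.
#' @return `curation_result` whose `records` carry the additional columns
#'   `wavelength`, `resolution_reported`, `n_parameters`, `n_restraints`,
#'   `n_constraints`, `z_max`.
#' @export
audit_cif_entries <- function(entries, rules = default_validity_rules()) {
  raw_sets <- lapply(entries, extract_items, tags = .survey_item_tags)
  res <- audit_corpus(raw_sets, rules)
  aux <- function(entry, tag) .parse_numeric_or_na(extract_items(entry, tag)[[1]])
  res$records$wavelength <- vapply(entries, aux, numeric(1),
                                   tag = "_diffrn_radiation_wavelength")
  res$records$resolution_reported <-
    vapply(entries, aux, numeric(1), tag = "_diffrn_reflns_resolution_max")
  res$records$n_parameters <- vapply(entries, aux, numeric(1),
                                     tag = "_refine_ls_number_parameters")
  res$records$n_restraints <- vapply(entries, aux, numeric(1),
                                     tag = "_refine_ls_number_restraints")
  res$records$n_constraints <- vapply(entries, aux, numeric(1),
                                      tag = "_refine_ls_number_constraints")
  res$records$z_max <- vapply(entries, function(e) {
    syms <- e$atom_sites$symbol
    if (length(syms) == 0L) return(NA_integer_)
    max(element_z(syms))
  }, integer(1))
  res
}

#' Export corpus tallies in a completeness-table layout
#'
#' One row per audited tag: completeness percentage, the validity range used,
#' and the non-numeric and out-of-range counts (reported separately).
#'
#' @param result a `curation_result`.
#' @param path optional CSV output path.
#' @return the table, invisibly when written.
#' @export
tallies_table <- function(result, path = NULL) {
  t <- result$tallies
  out <- data.frame(
    tag = t$tag,
    completeness_pct = round(t$completeness_pct, 1),
    range_used = sprintf("%g < x < %g", t$lower, t$upper),
    n_non_numeric = t$n_non_numeric,
    n_out_of_range = t$n_out_of_range,
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
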