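# Cohort distribution summaries, central intervals, percentile context and
# per-category tables.

#' Distribution summary of a cohort of curated values
#'
#' Quantiles use linear interpolation between closest order statistics
#' (quantile type 7); variance uses the n-1 denominator. The convention is
#' recorded in the result so exported tables are self-describing.
#'
#' @param values numeric vector of accepted metric values (`NA`s are
#'   dropped); must leave at least one value.
#' @return list of class `cohort_summary` with `n`, `mean`, `variance`, `sd`,
#'   `minimum`, `p10`, `lower_quartile`, `median`, `upper_quartile`, `p90`,
#'   `maximum`, `quantile_type`.
#' @export
summarize_cohort <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("summarize_cohort needs at least one value")
  q <- stats::quantile(v, probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                       type = 7, names = FALSE)
  structure(
    list(n = length(v),
         mean = mean(v),
         variance = if (length(v) > 1L) stats::var(v) else 0,
         sd = if (length(v) > 1L) stats::sd(v) else 0,
         minimum = min(v),
         p10 = q[1],
         lower_quartile = q[2],
         median = q[3],
         upper_quartile = q[4],
         p90 = q[5],
         maximum = max(v),
         quantile_type = 7L),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf(
    "<cohort_summary> n=%d mean=%.4g sd=%.4g | min=%.4g Q1=%.4g med=%.4g Q3=%.4g max=%.4g\n",
    x$n, x$mean, x$sd, x$minimum, x$lower_quartile, x$median,
    x$upper_quartile, x$maximum))
  invisible(x)
}

#' Percentile rank of a value in a reference cohort
#'
#' Mid-rank treatment of ties: `rank = 100 * (#below + #equal/2) / n`.
#'
#' @param value single numeric value.
#' @param cohort non-empty numeric reference cohort (`NA`s dropped).
#' @return percentile rank in `[0, 100]`.
#' @export
percentile_of <- function(value, cohort) {
  v <- cohort[!is.na(cohort)]
  if (length(v) == 0L) stop("percentile_of needs a non-empty cohort")
  100 * (sum(v < value) + 0.5 * sum(v == value)) / length(v)
}

#' Central interval of a cohort
#'
#' The `(quantile((1-coverage)/2), quantile((1+coverage)/2))` interval;
#' coverage 0.8 gives the (p10, p90) interval, coverage 0.5 the interquartile
#' range.
#'
#' @param values numeric vector (`NA`s dropped).
#' @param coverage fraction strictly between 0 and 1.
#' @return numeric vector `c(low, high)`.
#' @export
central_interval <- function(values, coverage) {
  if (!is.finite(coverage) || coverage <= 0 || coverage >= 1) {
    stop("coverage must lie strictly between 0 and 1")
  }
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("central_interval needs at least one value")
  stats::quantile(v, probs = c((1 - coverage) / 2, (1 + coverage) / 2),
                  type = 7, names = FALSE)
}

# The category axes and their levels (an entry counts on every axis).
.category_axes <- list(
  chemistry = c("organic", "metal_organic"),
  disordered = c(FALSE, TRUE),
  polymeric = c(FALSE, TRUE),
  pressure = c("ambient", "non_ambient"),
  radiation = c("xray", "neutron", "electron"),
  refinement_type = c("independent_atom", "aspherical")
)

.summary_row <- function(s) {
  data.frame(n = s$n, mean = s$mean, variance = s$variance, sd = s$sd,
             minimum = s$minimum, p10 = s$p10,
             lower_quartile = s$lower_quartile, median = s$median,
             upper_quartile = s$upper_quartile, p90 = s$p90,
             maximum = s$maximum, stringsAsFactors = FALSE)
}

.empty_summary_row <- function() {
  data.frame(n = 0L, mean = NA_real_, variance = NA_real_, sd = NA_real_,
             minimum = NA_real_, p10 = NA_real_, lower_quartile = NA_real_,
             median = NA_real_, upper_quartile = NA_real_, p90 = NA_real_,
             maximum = NA_real_, stringsAsFactors = FALSE)
}

#' Per-category distribution table for one metric
#'
#' One row per level of every category axis (plus an `all` row). Records and
#' labels are aligned by identifier; every entry contributes to each axis it
#' is classified on, and within an axis the per-level counts partition the
#' classified entries.
#'
#' @param records curated records data.frame (see [audit_cif_entries()]).
#' @param labels category data.frame (see [categorize_entries()]).
#' @param metric record column to summarize (e.g. `"r"`, `"shift_su"`).
#' @return data.frame with columns `axis`, `level`, `n`, summary fields.
#' @export
category_table <- function(records, labels, metric) {
  stopifnot(metric %in% names(records))
  m <- match(records$identifier, labels$identifier)
  if (anyNA(m)) {
    stop("labels are missing identifiers present in records: ",
         paste(utils::head(records$identifier[is.na(m)], 3), collapse = ", "))
  }
  lab <- labels[m, , drop = FALSE]
  vals <- records[[metric]]

  rows <- list()
  add <- function(axis, level, x) {
    x <- x[!is.na(x)]
    row <- if (length(x)) .summary_row(summarize_cohort(x)) else .empty_summary_row()
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(axis = axis, level = as.character(level),
                 stringsAsFactors = FALSE), row)
  }
  add("all", "all", vals)
  for (axis in names(.category_axes)) {
    for (level in .category_axes[[axis]]) {
      add(axis, level, vals[lab[[axis]] == level])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "metric") <- metric
  attr(out, "quantile_type") <- 7L
  out
}

# Default histogram bin widths per record column.
.default_binwidths <- c(r = 0.005, wr = 0.005, goof = 0.01, shift_su = 0.001,
                        rho_max = 0.05, rho_min = 0.05, theta_max = 1,
                        d = 0.01)

#' Fixed-width histogram bin counts for a metric
#'
#' @param values numeric vector (`NA`s dropped).
#' @param metric metric name used to pick a default bin width, or `NULL`.
#' @param binwidth explicit bin width (overrides the default).
#' @return data.frame with `bin_low`, `bin_high`, `count`.
#' @export
histogram_counts <- function(values, metric = NULL, binwidth = NULL) {
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop("histogram_counts needs at least one value")
  if (is.null(binwidth)) {
    binwidth <- if (!is.null(metric) && metric %in% names(.default_binwidths)) {
      .default_binwidths[[metric]]
    } else {
      diff(range(v)) / 50
    }
  }
  if (binwidth <= 0) stop("binwidth must be positive")
  lo <- floor(min(v) / binwidth) * binwidth
  hi <- ceiling(max(v) / binwidth) * binwidth
  if (hi <= lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  data.frame(bin_low = breaks[-length(breaks)], bin_high = breaks[-1L],
             count = counts)
}
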