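# Quantities derived from curated items: Bragg resolution, sin(theta)/lambda,
# the residual-density DTEST reference, and |rho_min|.

#' Real-space resolution from the Bragg equation
#'
#' `d = lambda / (2 sin theta_max)` with `theta_max` in degrees at the
#' interface (radians internally); the reciprocal-space measure
#' `sin(theta_max)/lambda = 1/(2d)` is recorded alongside.
#'
#' @param wavelength radiation wavelength in Angstrom (> 0).
#' @param theta_max maximum Bragg angle in degrees, strictly inside (0, 90).
#' @param source provenance flag, `"computed"` or `"reported"`.
#' @return list of class `resolution_value`: `d` (Angstrom),
#'   `sin_theta_over_lambda` (1/Angstrom), `source`.
#' @export
resolution_from_bragg <- function(wavelength, theta_max, source = "computed") {
  if (!is.finite(wavelength) || wavelength <= 0) {
    stop("wavelength must be a positive finite number")
  }
  if (!is.finite(theta_max) || theta_max <= 0 || theta_max >= 90) {
    stop("theta_max must lie strictly between 0 and 90 degrees")
  }
  s <- sin(theta_max * pi / 180)
  structure(list(d = wavelength / (2 * s),
                 sin_theta_over_lambda = s / wavelength,
                 source = source),
            class = "resolution_value")
}

#' Resolution of a metric record
#'
#' Prefers the directly reported `_diffrn_reflns_resolution_max` d-spacing
#' (rare in practice) over the Bragg computation from wavelength and
#' theta_max; returns `NULL` when neither route is available.
#'
#' @param record one row of a curated records data.frame (needs
#'   `wavelength`, `theta_max`, optionally `resolution_reported`).
#' @return a `resolution_value` or `NULL`.
#' @export
resolution_for_record <- function(record) {
  rep_d <- record$resolution_reported
  if (!is.null(rep_d) && length(rep_d) == 1L && !is.na(rep_d) && rep_d > 0) {
    return(structure(list(d = rep_d,
                          sin_theta_over_lambda = 1 / (2 * rep_d),
                          source = "reported"),
                     class = "resolution_value"))
  }
  lam <- record$wavelength
  th <- record$theta_max
  if (is.null(lam) || is.null(th) || is.na(lam) || is.na(th)) return(NULL)
  resolution_from_bragg(lam, th)
}

#' Residual-density reference threshold (DTEST)
#'
#' One tenth of the largest atomic number present in the structure, in
#' electrons per cubic Angstrom.
#'
#' @param z_max largest atomic number in the structure (integer >= 1).
#' @param multiplier threshold multiplier (default 0.1).
#' @return numeric threshold in e/A^3.
#' @export
dtest_threshold <- function(z_max, multiplier = 0.1) {
  if (any(!is.finite(z_max) | z_max < 1)) {
    stop("z_max must be a positive atomic number (>= 1)")
  }
  multiplier * z_max
}

#' Magnitude of the minimum residual density
#'
#' Curated minimum residual densities are non-positive; their absolute value
#' is used whenever minima and maxima are compared on one scale.
#'
#' @param rho_min minimum residual density in e/A^3 (<= 0 after curation).
#' @return `|rho_min|`.
#' @export
absolute_min_density <- function(rho_min) {
  abs(rho_min)
}
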