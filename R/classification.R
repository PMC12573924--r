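# Six-axis structure classification: chemistry, disorder, radiation source,
# pressure, polymeric, refinement type. Axes derivable from CIF content are
# derived; the rest come from an optional sidecar table or a flagged default.

#' Classification configuration
#'
#' @param pressure_threshold_kpa pressure above which an entry is classed
#'   non-ambient (default 200 kPa, about twice atmospheric; the convention is
#'   a package choice, not an archive-stated cutoff).
#' @param occupancy_eps tolerance distinguishing genuine partial occupancy
#'   from formatting noise (default 1e-6).
#' @param electron_wavelength_cutoff wavelengths (in Angstrom) below this are
#'   classed as electron diffraction (default 0.1 A; relativistic electron
#'   wavelengths at common accelerating voltages are ~0.02-0.04 A, an order
#'   of magnitude below any X-ray line in use).
#' @param aspherical_keywords case-insensitive keywords in
#'   `_refine_special_details` marking aspherical refinement.
#' @param disorder_keywords keywords marking unmodelled-density treatment.
#' @return named list of settings.
#' @export
classification_config <- function(pressure_threshold_kpa = 200,
                                  occupancy_eps = 1e-6,
                                  electron_wavelength_cutoff = 0.1,
                                  aspherical_keywords = c("multipole",
                                                          "hirshfeld atom",
                                                          "invariom",
                                                          "aspherical"),
                                  disorder_keywords = c("squeeze", "mask")) {
  list(pressure_threshold_kpa = pressure_threshold_kpa,
       occupancy_eps = occupancy_eps,
       electron_wavelength_cutoff = electron_wavelength_cutoff,
       aspherical_keywords = aspherical_keywords,
       disorder_keywords = disorder_keywords)
}

#' Classify entry chemistry from its element set
#'
#' Organic iff the element set is disjoint from the exclusion set (transition
#' metals, lanthanides, actinides, and Al, Ga, In, Tl, Ge, Sn, Pb, Sb, Bi,
#' Po); otherwise metal-organic.
#'
#' @param elements character vector of element symbols (charge suffixes
#'   tolerated); must be non-empty and recognized.
#' @return `"organic"` or `"metal_organic"`.
#' @export
classify_chemistry <- function(elements) {
  stopifnot(length(elements) >= 1L)
  syms <- normalize_element_symbol(elements)
  syms[syms == "D"] <- "H"
  unknown <- setdiff(syms, names(.element_z_map))
  if (length(unknown)) {
    stop("cannot classify chemistry: unrecognized element symbol(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(syms %in% organic_exclusion_elements())) "metal_organic" else "organic"
}

# Safe item access: NA_character_ when the tag is absent.
.item <- function(entry, tag) {
  unname(entry$items[tag][1])
}

# Lower-cased special-details text of an entry ("" when absent).
.special_details <- function(entry) {
  txt <- .item(entry, "_refine_special_details")
  if (is.na(txt)) "" else tolower(txt)
}

#' Detect structural disorder from CIF content
#'
#' True iff any non-hydrogen atom site has occupancy strictly below
#' `1 - occupancy_eps`, or a disorder assembly/group is populated, or the
#' refinement special-details text mentions an unmodelled-density keyword
#' (SQUEEZE/MASK, case-insensitive). With no atom sites and no details text
#' the result is `FALSE` with default provenance.
#'
#' @param entry a `cif_entry`.
#' @param config see [classification_config()].
#' @return logical, with attribute `provenance` (`"derived_from_cif"` or
#'   `"default"`).
#' @export
detect_disorder <- function(entry, config = classification_config()) {
  a <- entry$atom_sites
  details <- .special_details(entry)
  if (nrow(a) == 0L && !nzchar(details)) {
    return(structure(FALSE, provenance = "default"))
  }
  found <- FALSE
  if (nrow(a) > 0L) {
    occ <- vapply(a$occupancy, .parse_numeric_or_na, numeric(1),
                  USE.NAMES = FALSE)
    partial <- !a$hydrogen & !is.na(occ) & occ < 1 - config$occupancy_eps
    grouped <- !a$hydrogen & !(a$disorder_group %in% c(".", "?", ""))
    found <- any(partial) || any(grouped)
  }
  if (!found && nzchar(details)) {
    found <- any(vapply(config$disorder_keywords,
                        function(k) grepl(k, details, fixed = TRUE),
                        logical(1)))
  }
  structure(found, provenance = "derived_from_cif")
}

#' Infer the radiation source of an entry
#'
#' Uses `_diffrn_radiation_probe` when present; otherwise the wavelength
#' heuristic (below the electron cutoff -> electron, else X-ray); otherwise
#' X-ray by default with provenance recorded.
#'
#' @param entry a `cif_entry`.
#' @param config see [classification_config()].
#' @return one of `"xray"`, `"neutron"`, `"electron"`, with attribute
#'   `provenance`.
#' @export
infer_radiation <- function(entry, config = classification_config()) {
  probe <- .item(entry, "_diffrn_radiation_probe")
  if (!is.na(probe) && !(probe %in% c("?", "."))) {
    p <- tolower(probe)
    hits <- c(xray = grepl("x[-_ ]?ray", p),
              neutron = grepl("neutron", p),
              electron = grepl("electron", p))
    if (sum(hits) != 1L) {
      stop("contradictory or unrecognized radiation probe text: ", probe)
    }
    return(structure(names(hits)[hits], provenance = "derived_from_cif"))
  }
  lambda <- .parse_numeric_or_na(.item(entry, "_diffrn_radiation_wavelength"))
  if (!is.na(lambda) && lambda > 0) {
    src <- if (lambda < config$electron_wavelength_cutoff) "electron" else "xray"
    return(structure(src, provenance = "derived_from_cif"))
  }
  structure("xray", provenance = "default")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a sidecar label table
#'
#' @param path CSV with column `identifier` and any of `polymeric`
#'   (logical), `refinement_type` (`independent_atom`/`aspherical`),
#'   `pressure` (`ambient`/`non_ambient`).
#' @return data.frame keyed by identifier.
#' @export
read_sidecar <- function(path) {
  s <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("identifier" %in% names(s))
  s
}

.sidecar_lookup <- function(sidecar, id, field) {
  if (is.null(sidecar) || !(field %in% names(sidecar))) return(NULL)
  i <- match(id, sidecar$identifier)
  if (is.na(i)) {
    stop("sidecar has no row for entry identifier ", id)
  }
  v <- sidecar[[field]][i]
  if (is.na(v)) NULL else v
}

#' Assign the six category labels of an entry
#'
#' Chemistry, disorder and radiation are derived from CIF content; pressure
#' from `_diffrn_ambient_pressure` when present; refinement type from the
#' sidecar when provided, else a special-details keyword heuristic; polymeric
#' from the sidecar, else default `FALSE` (connectivity analysis is out of
#' scope). Every axis records its provenance. Axes are independent: an entry
#' contributes to every axis it matches.
#'
#' @param entry a `cif_entry`.
#' @param record optional metric-record row for the entry (unused by the
#'   default derivations, accepted for interface symmetry).
#' @param sidecar optional label table from [read_sidecar()]. A sidecar that
#'   carries a relevant column must have a row for the entry.
#' @param config see [classification_config()].
#' @return list of class `category_labels`: `identifier`, the six axis values
#'   and a named `provenance` vector.
#' @export
assign_categories <- function(entry, record = NULL, sidecar = NULL,
                              config = classification_config()) {
  prov <- c(chemistry = "derived_from_cif", disordered = "derived_from_cif",
            radiation = "derived_from_cif", pressure = "default",
            polymeric = "default", refinement_type = "default")

  syms <- entry$atom_sites$symbol
  chemistry <- if (length(syms) >= 1L) {
    classify_chemistry(syms)
  } else {
    prov[["chemistry"]] <- "default"
    "organic"
  }

  dis <- detect_disorder(entry, config)
  prov[["disordered"]] <- attr(dis, "provenance")
  rad <- infer_radiation(entry, config)
  prov[["radiation"]] <- attr(rad, "provenance")

  pressure <- "ambient"
  p_kpa <- .parse_numeric_or_na(.item(entry, "_diffrn_ambient_pressure"))
  side_p <- .sidecar_lookup(sidecar, entry$identifier, "pressure")
  if (!is.null(side_p)) {
    pressure <- side_p
    prov[["pressure"]] <- "sidecar"
  } else if (!is.na(p_kpa)) {
    pressure <- if (p_kpa > config$pressure_threshold_kpa) "non_ambient" else "ambient"
    prov[["pressure"]] <- "derived_from_cif"
  }

  refinement_type <- "independent_atom"
  side_rt <- .sidecar_lookup(sidecar, entry$identifier, "refinement_type")
  if (!is.null(side_rt)) {
    refinement_type <- side_rt
    prov[["refinement_type"]] <- "sidecar"
  } else {
    details <- .special_details(entry)
    if (nzchar(details) &&
        any(vapply(config$aspherical_keywords,
                   function(k) grepl(k, details, fixed = TRUE), logical(1)))) {
      refinement_type <- "aspherical"
      prov[["refinement_type"]] <- "derived_from_cif"
    }
  }

  polymeric <- FALSE
  side_poly <- .sidecar_lookup(sidecar, entry$identifier, "polymeric")
  if (!is.null(side_poly)) {
    polymeric <- as.logical(side_poly)
    prov[["polymeric"]] <- "sidecar"
  }

  structure(
    list(identifier = entry$identifier,
         chemistry = chemistry,
         disordered = as.logical(dis),
         radiation = as.character(rad),
         pressure = pressure,
         polymeric = polymeric,
         refinement_type = refinement_type,
         provenance = prov),
    class = "category_labels"
  )
}

#' Collect category labels for many entries into a data.frame
#'
#' @param entries list of `cif_entry` objects.
#' @param sidecar,config passed to [assign_categories()].
#' @return data.frame with one row per entry.
#' @export
categorize_entries <- function(entries, sidecar = NULL,
                               config = classification_config()) {
  rows <- lapply(entries, function(e) {
    l <- assign_categories(e, sidecar = sidecar, config = config)
    data.frame(identifier = l$identifier, chemistry = l$chemistry,
               disordered = l$disordered, radiation = l$radiation,
               pressure = l$pressure, polymeric = l$polymeric,
               refinement_type = l$refinement_type, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
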