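# Periodic-table data used for Zmax derivation and chemistry classification.

# Symbols indexed by atomic number 1..103.
.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn"
)

.element_z_map <- stats::setNames(seq_along(.element_symbols), .element_symbols)

#' Normalize an element symbol
#'
#' Strips charge/oxidation-state suffixes and site decorations from an
#' atom-site type symbol (e.g. `"Fe3+"`, `"O2-"`, `"C"`), returning the bare
#' periodic-table symbol with canonical capitalization.
#'
#' @param symbol character vector of raw symbols.
#' @return character vector of bare element symbols.
#' @export
normalize_element_symbol <- function(symbol) {
  s <- trimws(as.character(symbol))
  # drop anything after the leading letters (digits, +/- charges)
  s <- sub("^([A-Za-z]{1,2}).*$", "\\1", s)
  # canonical capitalization: first upper, second lower
  paste0(toupper(substring(s, 1, 1)), tolower(substring(s, 2)))
}

#' Atomic number of an element symbol
#'
#' @param symbol character vector of element symbols; charge suffixes are
#'   tolerated (`"Fe3+"` is iron). Deuterium (`"D"`) maps to Z = 1.
#' @return integer vector of atomic numbers; unknown symbols raise an error.
#' @export
element_z <- function(symbol) {
  s <- normalize_element_symbol(symbol)
  s[s == "D"] <- "H"
  z <- .element_z_map[s]
  if (anyNA(z)) {
    bad <- unique(s[is.na(z)])
    stop("unrecognized element symbol(s): ", paste(bad, collapse = ", "))
  }
  as.integer(z)
}

#' Elements that exclude a structure from the "organic" class
#'
#' The organic/metal-organic boundary used here follows the common structural
#' database convention: a structure is organic unless it contains a transition
#' metal (groups 3-12, periods 4-7, group 12 included), a lanthanide (La-Lu),
#' an actinide (Ac-Lr) or one of the ten p-block elements Al, Ga, In, Tl, Ge,
#' Sn, Pb, Sb, Bi, Po.
#'
#' @return character vector of excluded element symbols.
#' @export
organic_exclusion_elements <- function() {
  tm <- c(.element_symbols[21:30],   # Sc-Zn
          .element_symbols[39:48],   # Y-Cd
          .element_symbols[72:80],   # Hf-Hg (La counted below as lanthanide)
          .element_symbols[104:112]) # Rf-Cn
  lanthanides <- .element_symbols[57:71]   # La-Lu
  actinides <- .element_symbols[89:103]    # Ac-Lr
  pblock <- c("Al", "Ga", "In", "Tl", "Ge", "Sn", "Pb", "Sb", "Bi", "Po")
  sort(unique(c(tm, lanthanides, actinides, pblock)))
}
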