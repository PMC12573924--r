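# CIF 1.1 reading and writing.
#
# The reader targets archive-era single-crystal CIFs: tag/value pairs, loops,
# semicolon text fields, single/double quoting and '#' comments. It extracts
# raw value text byte-for-byte (quotes stripped, semicolon delimiters
# removed); no interpretation happens here.

.absent <- NA_character_

# The data items audited by the pipeline (Core CIF dictionary spellings,
# lower case; the "/" in the shift item is literal).
.survey_item_tags <- c(
  "_refine_ls_r_factor_gt",
  "_refine_ls_wr_factor_ref",
  "_refine_ls_shift/su_max",
  "_refine_diff_density_max",
  "_refine_diff_density_min",
  "_refine_ls_goodness_of_fit_ref",
  "_diffrn_reflns_theta_max"
)

.count_item_tags <- c(
  "_refine_ls_number_parameters",
  "_refine_ls_number_restraints",
  "_refine_ls_number_constraints"
)

.aux_item_tags <- c(
  "_diffrn_radiation_wavelength",
  "_diffrn_radiation_probe",
  "_diffrn_reflns_resolution_max",
  "_diffrn_ambient_pressure",
  "_refine_special_details"
)

#' Tags of the audited CIF data items
#'
#' @param which `"survey"` for the seven quality-metric items, `"counts"` for
#'   the parameter/restraint/constraint counts, `"aux"` for supporting items
#'   (wavelength, probe, reported resolution, pressure, special details), or
#'   `"all"`.
#' @return character vector of canonical (lower-case) tags.
#' @export
survey_tags <- function(which = c("survey", "counts", "aux", "all")) {
  which <- match.arg(which)
  switch(which,
    survey = .survey_item_tags,
    counts = .count_item_tags,
    aux = .aux_item_tags,
    all = c(.survey_item_tags, .count_item_tags, .aux_item_tags)
  )
}

# Split one line into raw tokens. Quoted strings are returned without their
# quotes; a '#' starting a token begins a comment that eats the rest of the
# line. Quote handling is the pragmatic CIF 1.1 subset: a quote character
# inside a quoted string is only terminal at the closing quote.
.tokenize_line <- function(line) {
  if (!nzchar(line)) return(character(0))
  # fast path: no quotes, no comment character
  if (!grepl("['\"#]", line, fixed = FALSE)) {
    toks <- strsplit(trimws(line), "[ \t]+")[[1]]
    return(toks[nzchar(toks)])
  }
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1) return(character(0))
  toks <- regmatches(line, list(m))[[1]]
  out <- character(0)
  for (tk in toks) {
    if (startsWith(tk, "#")) break  # comment to end of line
    first <- substring(tk, 1, 1)
    if ((first == "'" || first == "\"") && nchar(tk) >= 2 &&
        endsWith(tk, first)) {
      tk <- substring(tk, 2, nchar(tk) - 1)
    }
    out <- c(out, tk)
  }
  out
}

# Convert the lines of a file into a flat token stream. Semicolon text fields
# collapse to a single token (delimiters removed, inner newlines kept).
.cif_token_stream <- function(lines) {
  n <- length(lines)
  toks <- vector("list", n)
  i <- 1L
  k <- 0L
  while (i <= n) {
    ln <- lines[[i]]
    if (startsWith(ln, ";")) {
      j <- i + 1L
      buf <- substring(ln, 2)
      while (j <= n && !startsWith(lines[[j]], ";")) {
        buf <- c(buf, lines[[j]])
        j <- j + 1L
      }
      k <- k + 1L
      toks[[k]] <- paste(buf, collapse = "\n")
      i <- j + 1L
    } else {
      tl <- .tokenize_line(ln)
      if (length(tl)) {
        k <- k + 1L
        toks[[k]] <- tl
      }
      i <- i + 1L
    }
  }
  unlist(toks[seq_len(k)], use.names = FALSE)
}

.is_tag <- function(tok) startsWith(tok, "_")
.is_data <- function(tok) grepl("^data_", tok, ignore.case = TRUE)
.is_loop <- function(tok) tolower(tok) == "loop_"
.is_reserved <- function(tok) {
  .is_tag(tok) || .is_data(tok) || .is_loop(tok) ||
    tolower(tok) %in% c("stop_", "global_", "save_")
}

# Derive an element symbol from an atom-site label like "C12A" or "Fe1".
.symbol_from_label <- function(label) {
  lead <- sub("^([A-Za-z]{1,2}).*$", "\\1", label)
  two <- normalize_element_symbol(lead)
  if (two %in% names(.element_z_map) || two == "D") return(two)
  one <- normalize_element_symbol(substring(lead, 1, 1))
  one
}

.empty_atom_sites <- function() {
  data.frame(symbol = character(0), occupancy = character(0),
             hydrogen = logical(0), disorder_group = character(0),
             stringsAsFactors = FALSE)
}

.build_atom_sites <- function(tags, rows) {
  col <- function(tag) {
    j <- match(tag, tags)
    if (is.na(j)) NULL else rows[, j]
  }
  label <- col("_atom_site_label")
  type_symbol <- col("_atom_site_type_symbol")
  occupancy <- col("_atom_site_occupancy")
  dgroup <- col("_atom_site_disorder_group")
  nr <- nrow(rows)
  if (is.null(type_symbol)) {
    if (is.null(label)) return(.empty_atom_sites())
    symbol <- vapply(label, .symbol_from_label, character(1), USE.NAMES = FALSE)
  } else {
    symbol <- normalize_element_symbol(type_symbol)
  }
  if (is.null(occupancy)) occupancy <- rep("1", nr)
  if (is.null(dgroup)) dgroup <- rep(".", nr)
  data.frame(symbol = symbol, occupancy = occupancy,
             hydrogen = symbol %in% c("H", "D"),
             disorder_group = dgroup, stringsAsFactors = FALSE)
}

# Parse one block's token stream (tokens after its data_ header) into a
# cif_entry.
.parse_block_tokens <- function(identifier, toks, source) {
  items <- character(0)
  atom_sites <- .empty_atom_sites()
  warnings <- character(0)
  add_item <- function(tag, value) {
    if (tag %in% names(items)) {
      warnings <<- c(warnings,
                     sprintf("duplicate tag %s: first occurrence kept", tag))
    } else {
      items[[tag]] <<- value
    }
  }
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    tok <- toks[[i]]
    if (.is_loop(tok)) {
      # header
      j <- i + 1L
      ltags <- character(0)
      while (j <= n && .is_tag(toks[[j]])) {
        ltags <- c(ltags, tolower(toks[[j]]))
        j <- j + 1L
      }
      # body
      vals <- character(0)
      while (j <= n && !.is_reserved(toks[[j]])) {
        vals <- c(vals, toks[[j]])
        j <- j + 1L
      }
      nt <- length(ltags)
      if (nt == 0L) {
        warnings <- c(warnings, "loop_ with no tags: skipped")
      } else {
        nrows <- length(vals) %/% nt
        if (length(vals) %% nt != 0L) {
          warnings <- c(warnings, sprintf(
            "malformed loop (%d values for %d tags): complete rows salvaged",
            length(vals), nt))
        }
        if (nrows >= 1L) {
          rows <- matrix(vals[seq_len(nrows * nt)], nrow = nrows, ncol = nt,
                         byrow = TRUE)
          # first row also populates the flat item map (first occurrence wins)
          for (c_ in seq_len(nt)) add_item(ltags[[c_]], rows[1L, c_])
          if (any(startsWith(ltags, "_atom_site_"))) {
            atom_sites <- .build_atom_sites(ltags, rows)
          }
        } else if (length(vals) > 0L) {
          warnings <- c(warnings, "loop with a partial single row: dropped")
        }
      }
      i <- j
    } else if (.is_tag(tok)) {
      tag <- tolower(tok)
      if (i + 1L <= n && !.is_reserved(toks[[i + 1L]])) {
        add_item(tag, toks[[i + 1L]])
        i <- i + 2L
      } else {
        warnings <- c(warnings, sprintf("tag %s has no value", tag))
        i <- i + 1L
      }
    } else {
      warnings <- c(warnings, sprintf("stray value ignored: %s",
                                      substr(tok, 1, 40)))
      i <- i + 1L
    }
  }
  structure(
    list(identifier = identifier, items = items, atom_sites = atom_sites,
         source = source, parse_warnings = warnings),
    class = "cif_entry"
  )
}

#' Read every data block of a CIF 1.1 file
#'
#' Each `data_` block becomes one logical entry. Tags are lower-cased;
#' looped and non-looped items are both captured (for a looped tag the first
#' row's value populates the flat item map); the atom-site loop, when present,
#' is retained with element symbol, raw occupancy text and hydrogen flag.
#' Malformed loops do not abort the block: salvageable items are kept and a
#' parse warning is recorded on the entry.
#'
#' @param path path to a CIF file.
#' @return list of `cif_entry` objects (fields `identifier`, `items`,
#'   `atom_sites`, `source`, `parse_warnings`).
#' @export
read_cif_blocks <- function(path) {
  if (!file.exists(path)) stop("cannot read CIF file: ", path)
  lines <- readLines(path, warn = FALSE)
  toks <- .cif_token_stream(lines)
  starts <- which(vapply(toks, .is_data, logical(1)))
  if (length(starts) == 0L) {
    stop("no data block found in ", path)
  }
  ends <- c(starts[-1L] - 1L, length(toks))
  lapply(seq_along(starts), function(b) {
    id <- substring(toks[[starts[b]]], 6)
    if (!nzchar(id)) id <- sprintf("block_%d", b)
    body <- if (starts[b] + 1L <= ends[b]) {
      toks[(starts[b] + 1L):ends[b]]
    } else character(0)
    .parse_block_tokens(id, body, source = path)
  })
}

#' Read the first data block of a CIF file
#'
#' @inheritParams read_cif_blocks
#' @return a `cif_entry`; see [read_cif_blocks()] for multi-block files.
#' @export
read_cif <- function(path) {
  read_cif_blocks(path)[[1L]]
}

#' @export
print.cif_entry <- function(x, ...) {
  cat(sprintf("<cif_entry> %s (%d items, %d atom sites%s)\n",
              x$identifier, length(x$items), nrow(x$atom_sites),
              if (length(x$parse_warnings)) {
                sprintf(", %d parse warnings", length(x$parse_warnings))
              } else ""))
  invisible(x)
}

#' Project requested tags out of an entry
#'
#' A pure projection: one slot per requested tag, raw text unmodified, absent
#' tags marked with `NA` (the absent marker, distinct from an empty string).
#'
#' @param entry a `cif_entry`.
#' @param tags non-empty character vector of tags (any case).
#' @return named character vector (class `raw_item_set`) with attribute
#'   `identifier`; `NA` marks absence.
#' @export
extract_items <- function(entry, tags) {
  stopifnot(inherits(entry, "cif_entry"), length(tags) >= 1L)
  tags <- tolower(tags)
  out <- entry$items[tags]
  names(out) <- tags
  out[!(tags %in% names(entry$items))] <- .absent
  structure(out, identifier = entry$identifier, class = "raw_item_set")
}

# Quote a value for CIF output.
.format_cif_value <- function(value) {
  if (is.na(value)) return("?")
  if (grepl("\n", value, fixed = TRUE)) {
    return(paste0("\n;", value, "\n;"))
  }
  if (!nzchar(value)) return("''")
  if (grepl("[ \t]", value) || substring(value, 1, 1) %in% c("'", "\"", "_", "#", "$")) {
    q <- if (grepl("'", value, fixed = TRUE)) "\"" else "'"
    return(paste0(q, value, q))
  }
  value
}

#' Write a CIF entry back to CIF 1.1 text
#'
#' Inverse of [read_cif()] for audited content: re-reading the output yields
#' an identical item map and atom-site table. Used by the synthetic corpus
#' generator and the round-trip tests.
#'
#' @param entry a `cif_entry`.
#' @param path output path; when `NULL` the text is returned invisibly only.
#' @return character vector of lines, invisibly.
#' @export
write_cif_entry <- function(entry, path = NULL) {
  stopifnot(inherits(entry, "cif_entry"))
  lines <- c(paste0("data_", entry$identifier))
  atom_tags <- c("_atom_site_label", "_atom_site_type_symbol",
                 "_atom_site_occupancy", "_atom_site_disorder_group")
  for (tag in names(entry$items)) {
    if (tag %in% atom_tags) next  # emitted through the loop below
    lines <- c(lines, paste(tag, .format_cif_value(entry$items[[tag]])))
  }
  if (nrow(entry$atom_sites) > 0L) {
    lines <- c(lines, "loop_", " _atom_site_label", " _atom_site_type_symbol",
               " _atom_site_occupancy", " _atom_site_disorder_group")
    a <- entry$atom_sites
    label <- paste0(a$symbol, seq_len(nrow(a)))
    lines <- c(lines, paste(label, a$symbol, a$occupancy, a$disorder_group))
  }
  text <- unlist(strsplit(lines, "\n", fixed = TRUE))
  if (!is.null(path)) writeLines(text, path)
  invisible(text)
}
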