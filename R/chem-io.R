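#' Parse a SMILES string into a molecule record
#'
#' Parses and canonicalizes a single SMILES string through OpenBabel. The
#' returned canonical SMILES is the molecule's identity throughout the
#' package: two inputs denoting the same structure (e.g. `"CCO"` and
#' `"OCC"`) yield byte-identical `canonical_smiles`. Multi-fragment inputs
#' (salts, counter-ions) are reduced to the largest fragment by heavy-atom
#' count, since reference bioactivity libraries conventionally describe the
#' parent compound; a message is emitted when stripping occurs.
#'
#' Stereochemistry survives in `canonical_smiles` but the fingerprint panel
#' is purely 2D, so stereoisomers score identically downstream.
#'
#' @param smiles A single non-empty SMILES string.
#' @param name Optional molecule name carried through to outputs.
#' @return A one-row tibble with columns `canonical_smiles`, `name`,
#'   `source_format` ("SMILES").
#' @examples
#' \donttest{
#' parse_smiles("c1ccccc1", name = "benzene")
#' }
#' @export
parse_smiles <- function(smiles, name = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (is.na(smiles) || !nzchar(trimws(smiles))) {
    stop("invalid structure: empty SMILES input", call. = FALSE)
  }
  can <- canonicalize_smiles(smiles)
  if (is.na(can)) {
    stop("invalid structure: cannot parse SMILES ", sQuote(smiles), call. = FALSE)
  }
  tibble::tibble(
    canonical_smiles = can,
    name = as.character(name),
    source_format = "SMILES"
  )
}

# Canonicalize a vector of SMILES via OpenBabel; NA where parsing fails.
# Largest-fragment stripping happens here so identity is salt-free.
canonicalize_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    out <- ob_canonical(trimws(s))
    if (is.na(out)) return(NA_character_)
    if (grepl(".", out, fixed = TRUE)) {
      out <- largest_fragment(out)
      message("multi-fragment input reduced to largest fragment: ", out)
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

# One OpenBabel SMILES -> canonical SMILES round trip; NA on failure.
ob_canonical <- function(s) {
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
    error = function(e) ""
  )
  first <- strsplit(txt, "\n", fixed = TRUE)[[1]][1]
  if (is.na(first)) return(NA_character_)
  smi <- strsplit(first, "\t", fixed = TRUE)[[1]][1]
  if (is.na(smi) || !nzchar(trimws(smi))) NA_character_ else trimws(smi)
}

# Pick the fragment with the most heavy atoms (ties: first in SMILES order).
largest_fragment <- function(smi) {
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  counts <- vapply(frags, count_heavy_atoms, integer(1))
  frags[[which.max(counts)]]
}

# Heavy-atom count from a SMILES fragment: organic-subset symbols plus
# bracket atoms, hydrogens excluded. Sufficient for fragment ranking.
count_heavy_atoms <- function(smi) {
  n <- 0L
  in_bracket <- FALSE
  chars <- strsplit(smi, "")[[1]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      in_bracket <- TRUE
      is_h <- grepl("^\\[[0-9]*H[]+@H0-9+-]*\\]?",
                    paste(chars[i:min(i + 5L, length(chars))], collapse = ""))
      if (!is_h) n <- n + 1L
    } else if (ch == "]") {
      in_bracket <- FALSE
    } else if (!in_bracket) {
      if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I",
                    "b", "c", "n", "o", "p", "s")) {
        # two-letter Cl/Br are caught by their capital letter alone
        n <- n + 1L
      }
    }
    i <- i + 1L
  }
  n
}

#' Read molecules from a structure file
#'
#' Reads MDL MOL (single record), SDF (multi-record V2000) or a SMILES list
#' (one molecule per line, optional whitespace-separated name). Well-formed
#' records become molecule rows in file order; malformed records in a
#' multi-record file are collected into an error attribute instead of
#' aborting the batch.
#'
#' @param path Path to the structure file.
#' @param format One of `"MOL"`, `"SDF"`, `"SMILES"`. Defaults from the
#'   file extension (`.mol`, `.sdf`, anything else is read as a SMILES list).
#' @return A tibble with columns `canonical_smiles`, `name`,
#'   `source_format`, one row per well-formed record. The attribute
#'   `"errors"` holds a tibble (`record`, `input`, `reason`) describing
#'   records that failed to parse.
#' @export
read_molecules <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop("cannot read structure file: ", path, call. = FALSE)
  }
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mol = "MOL", sdf = "SDF", "SMILES")
  }
  format <- match.arg(toupper(format), c("MOL", "SDF", "SMILES"))
  switch(format,
    SMILES = read_smiles_list(path),
    MOL = read_sdf_records(path, "MOL"),
    SDF = read_sdf_records(path, "SDF")
  )
}

read_smiles_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- list()
  errs <- list()
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    smi <- toks[1]
    nm <- if (length(toks) > 1L) paste(toks[-1], collapse = " ") else NA_character_
    can <- suppressMessages(canonicalize_smiles(smi))
    if (is.na(can)) {
      errs[[length(errs) + 1L]] <- tibble::tibble(
        record = i, input = smi, reason = "unparseable SMILES")
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        canonical_smiles = can, name = nm, source_format = "SMILES")
    }
  }
  finish_molecule_table(rows, errs)
}

read_sdf_records <- function(path, source_format) {
  txt <- readLines(path, warn = FALSE)
  # split on the SDF record terminator; a bare MOL file is one record
  ends <- grep("^\\$\\$\\$\\$", txt)
  if (length(ends) == 0L) {
    starts <- 1L
    stops <- length(txt)
  } else {
    starts <- c(1L, head(ends, -1L) + 1L)
    stops <- ends - 1L
    keep <- starts <= stops
    starts <- starts[keep]
    stops <- stops[keep]
  }
  rows <- list()
  errs <- list()
  for (i in seq_along(starts)) {
    block <- txt[starts[i]:stops[i]]
    nm <- trimws(block[1])
    if (!nzchar(nm)) nm <- NA_character_
    molblock <- paste0(paste(block, collapse = "\n"), "\n$$$$\n")
    can <- tryCatch({
      out <- suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", molblock))
      first <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
      smi <- strsplit(first %||% "", "\t", fixed = TRUE)[[1]][1]
      if (is.na(smi) || !nzchar(trimws(smi))) NA_character_ else trimws(smi)
    }, error = function(e) NA_character_)
    if (!is.na(can) && grepl(".", can, fixed = TRUE)) {
      can <- largest_fragment(can)
    }
    if (is.na(can)) {
      errs[[length(errs) + 1L]] <- tibble::tibble(
        record = i, input = nm %||% "", reason = "malformed MOL/SDF record")
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        canonical_smiles = can, name = nm, source_format = source_format)
    }
  }
  finish_molecule_table(rows, errs)
}

finish_molecule_table <- function(rows, errs) {
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(canonical_smiles = character(), name = character(),
                   source_format = character())
  err_tbl <- if (length(errs)) dplyr::bind_rows(errs) else
    tibble::tibble(record = integer(), input = character(), reason = character())
  attr(out, "errors") <- err_tbl
  out
}

#' Parse-failure log of a molecule table
#'
#' @param molecules A tibble returned by [read_molecules()].
#' @return The tibble of per-record parse failures.
#' @export
molecule_errors <- function(molecules) {
  attr(molecules, "errors") %||%
    tibble::tibble(record = integer(), input = character(), reason = character())
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
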