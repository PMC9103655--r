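# Reference-data model: targets, ligands, activities, fingerprints.
# Raw tables follow a ChEMBL-style schema; curation applies the fixed
# filter battery and the library bundles curated tables with precomputed
# fingerprint panels.

ACTIVITY_TYPES <- c("IC50", "EC50", "Ki", "Kd")

REQUIRED_COLUMNS <- list(
  targets = c("target_id", "name", "target_type", "organism"),
  ligands = c("ligand_id", "canonical_smiles", "molecule_type", "prodrug_flag"),
  activities = c("ligand_id", "target_id", "standard_type", "standard_relation",
                 "standard_units", "standard_value", "confidence_score",
                 "activity_comment")
)

FILTER_RULES <- c("target_type", "molecule_type", "prodrug", "confidence",
                  "relation", "type", "units", "value", "comment")

#' Default inactivity comment terms
#'
#' Activity records whose comment contains (case-insensitively) any of
#' these terms are rejected during curation.
#'
#' @return Character vector of terms.
#' @export
default_inactivity_terms <- function() {
  c("inactive", "not active", "inconclusive")
}

check_schema <- function(tbl, what) {
  missing <- setdiff(REQUIRED_COLUMNS[[what]], names(tbl))
  if (length(missing)) {
    stop("schema error in ", what, " table: missing column ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Curate raw activity tables
#'
#' Applies the curation battery to ChEMBL-style raw tables, in a fixed
#' rule order: target_type (Single protein / Protein complex), ligand
#' molecule_type (Small_molecule), prodrug flag, confidence_score > 5,
#' standard_relation "=", standard_type in IC50/EC50/Ki/Kd, standard_units
#' "nM", positive standard_value, and no inactivity comment. Only activity
#' records passing every rule survive; surviving records are restricted to
#' targets and ligands that pass the entity-level rules.
#'
#' @param raw_targets,raw_ligands,raw_records Raw tibbles; see
#'   `ligfish:::REQUIRED_COLUMNS` for the expected columns.
#' @param inactivity_terms Terms whose presence in `activity_comment`
#'   (case-insensitive) rejects a record.
#' @return A list with `targets`, `ligands`, `activities` (curated
#'   tibbles) and `rejections`, a tibble of per-rule rejection counts in
#'   fixed rule order.
#' @export
filter_activity_records <- function(raw_targets, raw_ligands, raw_records,
                                    inactivity_terms = default_inactivity_terms()) {
  check_schema(raw_targets, "targets")
  check_schema(raw_ligands, "ligands")
  check_schema(raw_records, "activities")

  targets <- tibble::as_tibble(raw_targets)
  ligands <- tibble::as_tibble(raw_ligands)
  records <- tibble::as_tibble(raw_records)
  rejected <- stats::setNames(integer(length(FILTER_RULES)), FILTER_RULES)

  drop_records <- function(records, keep, rule) {
    keep[is.na(keep)] <- FALSE
    rejected[[rule]] <<- rejected[[rule]] + sum(!keep)
    records[keep, , drop = FALSE]
  }

  # entity-level rules first; records referencing a dropped entity are
  # counted under that entity's rule
  ok_target <- targets$target_type %in% c("Single protein", "Protein complex")
  targets <- targets[ok_target, , drop = FALSE]
  records <- drop_records(records, records$target_id %in% targets$target_id,
                          "target_type")

  ok_ligand <- ligands$molecule_type %in% "Small_molecule"
  ligands <- ligands[ok_ligand, , drop = FALSE]
  records <- drop_records(records, records$ligand_id %in% ligands$ligand_id,
                          "molecule_type")

  prodrug <- ligands$prodrug_flag
  ok_prodrug <- is.na(prodrug) | prodrug != 1
  ligands <- ligands[ok_prodrug, , drop = FALSE]
  records <- drop_records(records, records$ligand_id %in% ligands$ligand_id,
                          "prodrug")

  # record-level rules in fixed order
  records <- drop_records(records, records$confidence_score > 5, "confidence")
  records <- drop_records(records, records$standard_relation == "=", "relation")
  records <- drop_records(records, records$standard_type %in% ACTIVITY_TYPES, "type")
  records <- drop_records(records, records$standard_units == "nM", "units")
  records <- drop_records(records, records$standard_value > 0, "value")

  comment <- tolower(ifelse(is.na(records$activity_comment), "",
                            records$activity_comment))
  inactive <- rep(FALSE, nrow(records))
  for (term in inactivity_terms) {
    inactive <- inactive | grepl(tolower(term), comment, fixed = TRUE)
  }
  records <- drop_records(records, !inactive, "comment")

  list(
    targets = targets,
    ligands = ligands,
    activities = records,
    rejections = tibble::tibble(rule = FILTER_RULES, n_rejected = unname(rejected))
  )
}

#' Build a reference library from curated tables
#'
#' Precomputes the 13-kind fingerprint panel for every curated ligand
#' exactly once and assembles the four-table reference library used by
#' target fishing and bioactivity profiling. Ligands whose structure fails
#' to parse are dropped together with their activity records (logged in
#' the build metadata); targets or ligands left without any activity
#' record are dropped likewise, so the library has no orphans.
#'
#' @param curated A list from [filter_activity_records()] (or any list
#'   with curated `targets`, `ligands`, `activities` tibbles).
#' @param config Fingerprint configuration.
#' @param source_name,source_version Provenance strings recorded in the
#'   build metadata.
#' @param timestamp Build timestamp; pass a fixed value for reproducible
#'   bundles.
#' @return A `reference_library` object.
#' @export
build_reference_library <- function(curated,
                                    config = default_fingerprint_config(),
                                    source_name = "synthetic",
                                    source_version = "0",
                                    timestamp = format(Sys.time(), tz = "UTC")) {
  targets <- tibble::as_tibble(curated$targets)
  ligands <- tibble::as_tibble(curated$ligands)
  activities <- tibble::as_tibble(curated$activities)
  check_schema(targets, "targets")
  check_schema(ligands, "ligands")
  check_schema(activities, "activities")

  dropped <- tibble::tibble(ligand_id = character(), reason = character())

  can <- suppressMessages(canonicalize_smiles(ligands$canonical_smiles))
  bad <- is.na(can)
  if (any(bad)) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      ligand_id = ligands$ligand_id[bad], reason = "unparseable structure"))
  }
  ligands$canonical_smiles <- can
  ligands <- ligands[!bad, , drop = FALSE]
  activities <- activities[activities$ligand_id %in% ligands$ligand_id, , drop = FALSE]

  # no orphans: every ligand and target retains at least one record
  keep_lig <- ligands$ligand_id %in% activities$ligand_id
  if (any(!keep_lig)) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      ligand_id = ligands$ligand_id[!keep_lig], reason = "no activity records"))
  }
  ligands <- ligands[keep_lig, , drop = FALSE]
  targets <- targets[targets$target_id %in% activities$target_id, , drop = FALSE]
  activities <- activities[activities$target_id %in% targets$target_id, , drop = FALSE]

  panels <- NULL
  if (nrow(ligands)) {
    panels <- compute_panels(ligands$canonical_smiles, config,
                             ids = ligands$ligand_id)
  }

  lib <- structure(
    list(
      targets = targets,
      ligands = ligands,
      activities = activities,
      panels = panels,
      config = config,
      metadata = list(
        source_name = source_name,
        source_version = source_version,
        built = timestamp,
        n_targets = nrow(targets),
        n_ligands = nrow(ligands),
        n_activities = nrow(activities),
        dropped_ligands = dropped,
        filter_rules = FILTER_RULES
      )
    ),
    class = "reference_library"
  )
  assert_library_integrity(lib)
  lib
}

assert_library_integrity <- function(lib) {
  act <- lib$activities
  if (nrow(act)) {
    stopifnot(
      all(act$ligand_id %in% lib$ligands$ligand_id),
      all(act$target_id %in% lib$targets$target_id),
      all(lib$targets$target_id %in% act$target_id)
    )
  }
  if (!is.null(lib$panels)) {
    stopifnot(identical(lib$panels$ids, lib$ligands$ligand_id))
  }
  invisible(TRUE)
}

#' @export
print.reference_library <- function(x, ...) {
  cat("<reference_library> ", nrow(x$targets), " targets, ", nrow(x$ligands),
      " ligands, ", nrow(x$activities), " activity records\n",
      "  source: ", x$metadata$source_name, " ", x$metadata$source_version,
      " (built ", x$metadata$built, ")\n", sep = "")
  invisible(x)
}

#' Best experimental activity for a ligand-target pair
#'
#' The most potent (minimum nM) curated value among all records of the
#' given activity type for the pair; `NA` when no record of that type
#' exists.
#'
#' @param library A `reference_library`.
#' @param ligand_id,target_id Identifiers present in the library.
#' @param standard_type One of `"IC50"`, `"EC50"`, `"Ki"`, `"Kd"`.
#' @return A single numeric value in nM, or `NA_real_`.
#' @export
best_activity <- function(library, ligand_id, target_id, standard_type) {
  stopifnot(inherits(library, "reference_library"))
  if (!ligand_id %in% library$ligands$ligand_id) {
    stop("unknown ligand_id: ", ligand_id, call. = FALSE)
  }
  if (!target_id %in% library$targets$target_id) {
    stop("unknown target_id: ", target_id, call. = FALSE)
  }
  standard_type <- match.arg(standard_type, ACTIVITY_TYPES)
  v <- library$activities$standard_value[
    library$activities$ligand_id == ligand_id &
    library$activities$target_id == target_id &
    library$activities$standard_type == standard_type]
  if (!length(v)) NA_real_ else min(v)
}

# Best activity of a ligand at a target across all four types; returns a
# one-row tibble (type, value_nM) or an all-NA row when none exists.
best_activity_any <- function(library, ligand_id, target_id) {
  act <- library$activities
  rows <- act[act$ligand_id == ligand_id & act$target_id == target_id, , drop = FALSE]
  if (!nrow(rows)) {
    return(tibble::tibble(best_type = NA_character_, best_value_nM = NA_real_))
  }
  i <- which.min(rows$standard_value)
  tibble::tibble(best_type = rows$standard_type[i],
                 best_value_nM = rows$standard_value[i])
}

LIBRARY_LAYOUT_VERSION <- "1"

#' Save a reference library bundle
#'
#' Writes the library as a single-directory bundle: a JSON manifest (layout
#' version, build metadata, fingerprint configuration), the three curated
#' tables as CSV, and the packed fingerprint panels as a hex-encoded TSV.
#' The bundle is plain text and round-trips bit-identically through
#' [load_library()].
#'
#' @param library A `reference_library`.
#' @param path Directory to create (must not already contain a bundle
#'   unless `overwrite = TRUE`).
#' @param overwrite Replace an existing bundle.
#' @return `path`, invisibly.
#' @export
save_library <- function(library, path, overwrite = FALSE) {
  stopifnot(inherits(library, "reference_library"))
  if (dir.exists(path) && file.exists(file.path(path, "manifest.json")) &&
      !overwrite) {
    stop("bundle already exists at ", path, " (use overwrite = TRUE)",
         call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    layout_version = LIBRARY_LAYOUT_VERSION,
    metadata = library$metadata[setdiff(names(library$metadata), "dropped_ligands")],
    dropped_ligands = library$metadata$dropped_ligands,
    fingerprint_config = library$config,
    kinds = if (is.null(library$panels)) character() else library$panels$kinds
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(library$targets, file.path(path, "targets.csv"),
                   row.names = FALSE)
  utils::write.csv(library$ligands, file.path(path, "ligands.csv"),
                   row.names = FALSE)
  act_out <- library$activities
  # full double precision so bundles round-trip bit-identically
  act_out$standard_value <- sprintf("%.17g", act_out$standard_value)
  utils::write.csv(act_out, file.path(path, "activities.csv"),
                   row.names = FALSE)
  con <- file(file.path(path, "fingerprints.tsv"), "w")
  on.exit(close(con))
  writeLines("ligand_id\tkind\tn_on\thex", con)
  if (!is.null(library$panels)) {
    p <- library$panels
    for (k in p$kinds) {
      hex <- apply(p$bits[[k]], 2, function(col) paste(format(col), collapse = ""))
      writeLines(paste(p$ids, k, p$n_on[[k]], hex, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Load a reference library bundle
#'
#' @param path Bundle directory written by [save_library()].
#' @return A `reference_library`.
#' @export
load_library <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) {
    stop("not a library bundle (no manifest.json): ", path, call. = FALSE)
  }
  manifest <- tryCatch(jsonlite::read_json(mf),
                       error = function(e) stop("incompatible or corrupt bundle manifest: ",
                                                conditionMessage(e), call. = FALSE))
  if (!identical(manifest$layout_version, LIBRARY_LAYOUT_VERSION)) {
    stop("incompatible bundle layout version ",
         sQuote(manifest$layout_version %||% "<missing>"), "; this build reads version ",
         LIBRARY_LAYOUT_VERSION, call. = FALSE)
  }
  needed <- file.path(path, c("targets.csv", "ligands.csv", "activities.csv",
                              "fingerprints.tsv"))
  if (!all(file.exists(needed))) {
    stop("incompatible bundle: missing files ",
         paste(basename(needed[!file.exists(needed)]), collapse = ", "),
         call. = FALSE)
  }
  read_tbl <- function(f, coltypes) {
    tibble::as_tibble(utils::read.csv(file.path(path, f),
                                      colClasses = coltypes,
                                      stringsAsFactors = FALSE))
  }
  targets <- read_tbl("targets.csv", c(target_id = "character", name = "character",
                                       target_type = "character", organism = "character"))
  ligands <- read_tbl("ligands.csv", c(ligand_id = "character",
                                       canonical_smiles = "character",
                                       molecule_type = "character",
                                       prodrug_flag = "integer"))
  activities <- read_tbl("activities.csv",
                         c(ligand_id = "character", target_id = "character",
                           standard_type = "character", standard_relation = "character",
                           standard_units = "character", standard_value = "character",
                           confidence_score = "integer", activity_comment = "character"))
  activities$standard_value <- as.numeric(activities$standard_value)
  config <- restore_config(manifest$fingerprint_config)

  fp <- utils::read.delim(file.path(path, "fingerprints.tsv"),
                          stringsAsFactors = FALSE, colClasses = "character")
  panels <- NULL
  if (nrow(fp)) {
    kinds <- names(config)
    ids <- ligands$ligand_id
    nbits <- vapply(config, function(k) as.integer(k$nbits), integer(1))
    bits <- list(); n_on <- list()
    for (k in kinds) {
      rows <- fp[fp$kind == k, , drop = FALSE]
      if (!identical(rows$ligand_id, ids)) {
        rows <- rows[match(ids, rows$ligand_id), , drop = FALSE]
      }
      if (anyNA(rows$hex)) {
        stop("incompatible bundle: fingerprint block incomplete for kind ",
             sQuote(k), call. = FALSE)
      }
      mat <- vapply(rows$hex, hex_to_raw, raw(nbits[[k]] / 8L), USE.NAMES = FALSE)
      bits[[k]] <- matrix(mat, nrow = nbits[[k]] / 8L)
      n_on[[k]] <- as.integer(rows$n_on)
    }
    panels <- structure(
      list(ids = ids, smiles = ligands$canonical_smiles, kinds = kinds,
           nbits = nbits, bits = bits, n_on = n_on, config = config),
      class = "fp_set")
  }

  dropped <- manifest$dropped_ligands
  dropped_tbl <- if (length(dropped)) {
    dplyr::bind_rows(lapply(dropped, tibble::as_tibble))
  } else {
    tibble::tibble(ligand_id = character(), reason = character())
  }

  lib <- structure(
    list(targets = targets, ligands = ligands, activities = activities,
         panels = panels, config = config,
         metadata = c(restore_metadata(lapply(manifest$metadata, unlist_scalar)),
                      list(dropped_ligands = dropped_tbl,
                           filter_rules = FILTER_RULES))),
    class = "reference_library")
  assert_library_integrity(lib)
  lib
}

unlist_scalar <- function(x) if (is.list(x) && length(x) == 1L) x[[1]] else x

restore_metadata <- function(md) {
  md <- md[setdiff(names(md), "filter_rules")]
  for (f in c("n_targets", "n_ligands", "n_activities")) {
    if (!is.null(md[[f]])) md[[f]] <- as.integer(md[[f]])
  }
  md
}

hex_to_raw <- function(hex) {
  n <- nchar(hex) / 2L
  as.raw(strtoi(substring(hex, 2L * seq_len(n) - 1L, 2L * seq_len(n)), 16L))
}

# JSON round-trip of the config turns integers into lists; restore types.
restore_config <- function(cfg) {
  out <- lapply(cfg, function(k) {
    list(backend = k$backend[[1]], nbits = as.integer(k$nbits[[1]]),
         params = lapply(k$params, function(p) {
           p <- p[[1]] %||% p
           if (is.character(p) || is.logical(p)) p else
             if (is.numeric(p) && p == as.integer(p)) as.integer(p) else p
         }))
  })
  names(out) <- names(cfg)
  out
}
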