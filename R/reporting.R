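# Report assembly and rendering. One PredictionReport feeds both output
# contracts: a schema-stable JSON document and a paginated PDF mirroring
# the platform-style report (query page, summary table, per-target
# similarity-analysis sections).

#' Assemble a prediction report
#'
#' Builds the renderable report object from a fishing or profiling result:
#' summary rows, one similarity-analysis detail section per reported
#' target, and provenance (library metadata plus a parameter snapshot).
#'
#' @param result A `fishing_result` or `profile_result`.
#' @param library The `reference_library` the result was computed against.
#' @param top_n_evidence Evidence rows per detail section.
#' @param fishing_params_ Parameters used for the similarity-analysis
#'   sections (defaults to the result's own parameters for fishing
#'   results).
#' @return A `prediction_report` object.
#' @export
prediction_report <- function(result, library, top_n_evidence = 5L,
                              fishing_params_ = NULL) {
  stopifnot(inherits(result, c("fishing_result", "profile_result")),
            inherits(library, "reference_library"))
  method <- if (inherits(result, "fishing_result")) "target_fishing" else
    "bioactivity_profiling"
  query_smiles <- attr(result, "query_smiles")
  params <- attr(result, "params")
  fp <- fishing_params_ %||% if (method == "target_fishing") params else
    fishing_params()

  detail <- list()
  if (nrow(result)) {
    qp <- compute_panels(query_smiles, library$config)
    for (tid in result$target_id) {
      detail[[tid]] <- similarity_analysis(qp, tid, library, fp,
                                           top_n = top_n_evidence)
    }
  }

  summary_rows <- if (method == "target_fishing") {
    tibble::as_tibble(result)[, c("rank", "target_id", "name", "score",
                                  "reliable")]
  } else {
    tibble::as_tibble(result)[, c("rank", "target_id", "name", "IC50", "EC50",
                                  "Ki", "Kd", "sigma_p", "best_type")]
  }

  structure(
    list(
      query = list(canonical_smiles = query_smiles),
      method = method,
      summary_rows = summary_rows,
      detail_sections = detail,
      provenance = list(
        library = library$metadata[c("source_name", "source_version", "built",
                                     "n_targets", "n_ligands", "n_activities")],
        params = unclass(params),
        fishing_params = unclass(fp)
      )
    ),
    class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report> ", x$method, ", ", nrow(x$summary_rows),
      " summary rows, ", length(x$detail_sections), " detail sections\n",
      sep = "")
  invisible(x)
}

# Named vectors become named lists of scalars so that serialize -> parse
# -> serialize is a fixed point of the JSON text.
canonicalize_json <- function(x) {
  if (is.list(x)) return(lapply(x, canonicalize_json))
  if (!is.null(names(x)) || length(x) != 1L) return(lapply(
    stats::setNames(as.list(x), names(x)), identity))
  x
}

# canonical plain-list form of a report (stable key order, JSON-ready)
report_to_list <- function(report) {
  kinds <- fingerprint_kinds()
  detail <- lapply(names(report$detail_sections), function(tid) {
    sec <- report$detail_sections[[tid]]
    list(
      target_id = tid,
      evidence = lapply(seq_len(nrow(sec)), function(i) {
        list(
          ligand_id = sec$ligand_id[[i]],
          canonical_smiles = sec$canonical_smiles[[i]],
          mean_similarity = sec$mean_similarity[[i]],
          similarities = as.list(stats::setNames(sec$similarities[[i]], kinds)),
          over_threshold = as.list(stats::setNames(sec$over_threshold[[i]], kinds)),
          best_type = sec$best_type[[i]],
          best_value_nM = sec$best_value_nM[[i]]
        )
      })
    )
  })
  list(
    document = "prediction_report",
    layout_version = LIBRARY_LAYOUT_VERSION,
    query = report$query,
    method = report$method,
    provenance = canonicalize_json(report$provenance),
    summary = lapply(seq_len(nrow(report$summary_rows)), function(i) {
      as.list(report$summary_rows[i, ])
    }),
    detail = detail
  )
}

#' Render a report as structured JSON
#'
#' Emits the report as a JSON document with stable key order: query block,
#' method, provenance (parameter snapshot), ordered summary rows, and
#' per-target evidence arrays with the 13 similarities, their
#' over/under-threshold flags and best experimental values. The document
#' validates against the schema shipped in `inst/schema/` and round-trips
#' losslessly: serialize, parse, serialize is byte-identical.
#'
#' @param report A `prediction_report`.
#' @param path Optional file to write.
#' @return The JSON text, invisibly when `path` is given.
#' @export
render_structured <- function(report, path = NULL) {
  stopifnot(inherits(report, "prediction_report"))
  doc <- report_to_list(report)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null", pretty = TRUE)
  problems <- validate_structured(jsonlite::fromJSON(json, simplifyVector = FALSE))
  if (length(problems)) {
    stop("internal consistency error: rendered report violates its schema: ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Parse a structured report document
#'
#' @param json JSON text or a path to a JSON file.
#' @return The parsed report list (canonical plain-list form).
#' @export
parse_structured <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  problems <- validate_structured(doc)
  if (length(problems)) {
    stop("document does not validate as a prediction report: ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  doc
}

# Minimal structural validation of the canonical document form; returns a
# character vector of problems (empty when valid).
validate_structured <- function(doc) {
  problems <- character()
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(identical(doc$document, "prediction_report"), "document tag missing")
  need(doc$method %in% c("target_fishing", "bioactivity_profiling"),
       "unknown method")
  need(is.character(doc$query$canonical_smiles %||% NULL) ||
         is.character(doc$query$canonical_smiles[[1]] %||% NULL),
       "query SMILES missing")
  need(is.list(doc$summary), "summary rows missing")
  need(is.list(doc$detail), "detail sections missing")
  summary_ids <- vapply(doc$summary, function(r) as.character(r$target_id),
                        character(1))
  detail_ids <- vapply(doc$detail, function(d) as.character(d$target_id),
                       character(1))
  need(all(summary_ids %in% detail_ids),
       "summary row without a detail section")
  kinds <- fingerprint_kinds()
  for (d in doc$detail) {
    for (ev in d$evidence) {
      need(identical(names(ev$similarities), kinds),
           paste0("evidence similarities malformed for ", d$target_id))
      need(identical(names(ev$over_threshold), kinds),
           paste0("evidence flags malformed for ", d$target_id))
    }
  }
  problems
}

#' Render a report as a paginated PDF
#'
#' Page 1 shows the query structure (2D depiction) and its SMILES; page 2
#' the summary table (score and reliability for fishing; predicted
#' IC50/EC50/Ki/Kd and sigma_p for profiling); each following page is one
#' per-target similarity-analysis section with over/under-threshold
#' markers and best experimental values. Layout is deterministic for a
#' fixed report. A depiction failure degrades to a placeholder, never a
#' crash.
#'
#' @param report A `prediction_report`.
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
render_document <- function(report, path) {
  stopifnot(inherits(report, "prediction_report"))
  grDevices::pdf(path, width = 8.3, height = 11.7, onefile = TRUE)
  on.exit(grDevices::dev.off())

  # page 1: query
  graphics::par(mar = c(2, 2, 4, 2))
  depicted <- tryCatch({
    sdf <- ChemmineR::smiles2sdf(report$query$canonical_smiles)
    ChemmineR::plotStruc(sdf[[1]], atomcex = 0.9)
    TRUE
  }, error = function(e) FALSE)
  if (!depicted) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "[structure depiction unavailable]")
    warning("depiction failed; placeholder used", call. = FALSE)
  }
  graphics::mtext(method_title(report$method), side = 3, line = 2, cex = 1.4)
  graphics::mtext(paste("Query SMILES:", report$query$canonical_smiles),
                  side = 1, line = 0, cex = 0.9)

  # page 2: summary table
  tbl <- format_summary_table(report)
  draw_text_page(c(paste0(method_title(report$method), " - summary"), "", tbl))

  # detail pages
  for (tid in names(report$detail_sections)) {
    sec <- report$detail_sections[[tid]]
    lines <- format_detail_section(tid, sec, report)
    draw_text_page(lines)
  }
  invisible(path)
}

method_title <- function(method) {
  if (method == "target_fishing") "Target fishing report" else
    "Bioactivity profiling report"
}

signif3 <- function(x) {
  ifelse(is.na(x), "-", formatC(signif(x, 3), format = "g", digits = 3))
}

format_summary_table <- function(report) {
  sr <- report$summary_rows
  if (report$method == "target_fishing") {
    header <- sprintf("%-5s %-12s %-28s %-6s %-8s", "rank", "target", "name",
                      "score", "reliable")
    rows <- sprintf("%-5d %-12s %-28s %-6d %-8s", sr$rank, sr$target_id,
                    substr(sr$name, 1, 28), sr$score,
                    ifelse(sr$reliable, "yes", "not"))
  } else {
    header <- sprintf("%-5s %-12s %-22s %9s %9s %9s %9s %8s", "rank", "target",
                      "name", "IC50", "EC50", "Ki", "Kd", "sigma_p")
    rows <- sprintf("%-5d %-12s %-22s %9s %9s %9s %9s %8.2f", sr$rank,
                    sr$target_id, substr(sr$name, 1, 22), signif3(sr$IC50),
                    signif3(sr$EC50), signif3(sr$Ki), signif3(sr$Kd),
                    sr$sigma_p)
  }
  c(header, rows)
}

format_detail_section <- function(tid, sec, report) {
  lines <- c(paste0("Similarity analysis - ", tid), "")
  header <- sprintf("%-12s %8s %6s  %-29s %-10s %10s", "ligand", "mean_sim",
                    "n_over", "flags (13 kinds, + over / . under)",
                    "best_type", "best_nM")
  rows <- vapply(seq_len(nrow(sec)), function(i) {
    flags <- paste(ifelse(sec$over_threshold[[i]], "+", "."), collapse = " ")
    sprintf("%-12s %8.3f %6d  %-29s %-10s %10s", sec$ligand_id[[i]],
            sec$mean_similarity[[i]], sec$n_over[[i]], flags,
            ifelse(is.na(sec$best_type[[i]]), "-", sec$best_type[[i]]),
            signif3(sec$best_value_nM[[i]]))
  }, character(1))
  c(lines, header, rows)
}

draw_text_page <- function(lines) {
  graphics::par(mar = c(1, 1, 1, 1))
  graphics::plot.new()
  n <- length(lines)
  y <- 1 - (seq_len(n) - 0.5) / max(n, 40)
  graphics::text(0.01, y, lines, adj = c(0, 0.5), family = "mono", cex = 0.7)
}
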