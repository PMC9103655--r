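# Multi-fingerprint consensus target fishing.
#
# For each protein target the query's best Tanimoto similarity to the
# target's known ligands is taken per fingerprint kind; the consensus
# score (0-13) counts the kinds whose best similarity reaches that kind's
# threshold. Identity with a known ligand therefore attains the maximum
# score of 13.

#' Target-fishing parameters
#'
#' @param thresholds Per-kind similarity thresholds: either a single value
#'   applied to all 13 kinds or a fully named vector over
#'   [fingerprint_kinds()]. Default 0.6 everywhere.
#' @param min_reported_targets Minimum number of targets in the report
#'   (default 30); all reliable targets are always shown even beyond this.
#' @param reliability_min_score Minimum consensus score for a prediction
#'   to be flagged reliable (default 7, a strict majority of the 13 kinds).
#' @return A `fishing_params` list.
#' @export
fishing_params <- function(thresholds = 0.6, min_reported_targets = 30L,
                           reliability_min_score = 7L) {
  kinds <- fingerprint_kinds()
  if (length(thresholds) == 1L && is.null(names(thresholds))) {
    thresholds <- stats::setNames(rep(as.numeric(thresholds), length(kinds)), kinds)
  }
  if (!setequal(names(thresholds), kinds)) {
    stop("thresholds must cover every fingerprint kind", call. = FALSE)
  }
  thresholds <- thresholds[kinds]
  stopifnot(all(thresholds >= 0), all(thresholds <= 1),
            min_reported_targets >= 1L,
            reliability_min_score >= 0L, reliability_min_score <= 13L)
  structure(
    list(thresholds = thresholds,
         min_reported_targets = as.integer(min_reported_targets),
         reliability_min_score = as.integer(reliability_min_score)),
    class = "fishing_params")
}

#' Consensus score of one target
#'
#' @param query_panel An `fp_set` with the query's panel.
#' @param target_panels An `fp_set` with the panels of the target's known
#'   ligands (at least one).
#' @param params [fishing_params()].
#' @return A list with `score` (integer 0-13) and `per_kind_best`, the
#'   13-vector of best similarities per kind.
#' @export
score_target <- function(query_panel, target_panels, params = fishing_params()) {
  stopifnot(inherits(query_panel, "fp_set"), inherits(target_panels, "fp_set"))
  if (length(target_panels$ids) == 0L) {
    stop("target has no reference ligand panels", call. = FALSE)
  }
  sims <- similarity_matrix(query_panel, target_panels)
  per_kind_best <- apply(sims, 1, max)
  score <- sum(per_kind_best >= params$thresholds)
  list(score = as.integer(score), per_kind_best = per_kind_best)
}

#' Reliability call for a consensus score
#'
#' @param score Integer consensus score in 0-13.
#' @param params [fishing_params()].
#' @return `TRUE` when `score >= reliability_min_score`.
#' @export
assess_reliability <- function(score, params = fishing_params()) {
  stopifnot(all(score >= 0L), all(score <= 13L))
  score >= params$reliability_min_score
}

#' Fish protein targets for a query molecule
#'
#' Scores every target in the reference library against the query and
#' returns the ranked report: descending consensus score, ties broken by
#' descending mean per-kind best similarity and then by target id. The
#' report holds `max(min_reported_targets, number of reliable targets)`
#' rows, capped at the library's target count, so all reliable targets are
#' always shown.
#'
#' @param query A one-row molecule tibble, a SMILES string, or a
#'   precomputed single-panel `fp_set`.
#' @param library A `reference_library`.
#' @param params [fishing_params()].
#' @return A `fishing_result` tibble: `rank`, `target_id`, `name`,
#'   `score`, `reliable`, `mean_best`, and `per_kind_best` (list column of
#'   named 13-vectors). Attributes carry the query SMILES and parameters.
#' @export
fish_targets <- function(query, library, params = fishing_params()) {
  stopifnot(inherits(library, "reference_library"))
  if (nrow(library$targets) == 0L) {
    stop("reference library holds no targets", call. = FALSE)
  }
  qp <- as_query_panel(query, library$config)

  scored <- purrr::map_dfr(library$targets$target_id, function(tid) {
    st <- score_target(qp, target_panel_set(library, tid), params)
    tibble::tibble(
      target_id = tid,
      score = st$score,
      mean_best = mean(st$per_kind_best),
      per_kind_best = list(st$per_kind_best)
    )
  })
  scored <- dplyr::left_join(scored,
                             library$targets[, c("target_id", "name")],
                             by = "target_id")
  scored$reliable <- assess_reliability(scored$score, params)
  scored <- scored[order(-scored$score, -scored$mean_best, scored$target_id), ]

  n_show <- min(nrow(scored),
                max(params$min_reported_targets, sum(scored$reliable)))
  out <- scored[seq_len(n_show),
                c("target_id", "name", "score", "reliable", "mean_best",
                  "per_kind_best")]
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1L)
  attr(out, "query_smiles") <- qp$smiles[[1]]
  attr(out, "params") <- params
  class(out) <- c("fishing_result", class(out))
  out
}

#' Similarity-analysis evidence for one fished target
#'
#' The target's known ligands ranked by descending mean similarity across
#' the 13 kinds, with per-kind similarities, over/under-threshold flags
#' and each ligand's best experimental activity (most potent record across
#' the four activity types).
#'
#' @inheritParams fish_targets
#' @param target_id A target present in the library.
#' @param top_n Number of evidence rows (all ligands when fewer).
#' @return A tibble: `ligand_id`, `canonical_smiles`, `mean_similarity`,
#'   `n_over`, `similarities` and `over_threshold` (list columns, kind
#'   order), `best_type`, `best_value_nM`.
#' @export
similarity_analysis <- function(query, target_id, library,
                                params = fishing_params(), top_n = 10L) {
  stopifnot(inherits(library, "reference_library"))
  if (!target_id %in% library$targets$target_id) {
    stop("unknown target_id: ", target_id, call. = FALSE)
  }
  qp <- as_query_panel(query, library$config)
  tp <- target_panel_set(library, target_id)
  sims <- similarity_matrix(qp, tp)

  rows <- purrr::map_dfr(seq_along(tp$ids), function(j) {
    s <- sims[, j]
    dplyr::bind_cols(
      tibble::tibble(
        ligand_id = tp$ids[[j]],
        canonical_smiles = tp$smiles[[j]],
        mean_similarity = mean(s),
        n_over = sum(s >= params$thresholds),
        similarities = list(s),
        over_threshold = list(s >= params$thresholds)
      ),
      best_activity_any(library, tp$ids[[j]], target_id)
    )
  })
  rows <- rows[order(-rows$mean_similarity, rows$ligand_id), ]
  rows <- rows[seq_len(min(top_n, nrow(rows))), ]
  rows
}

# Panels of a target's ligands (ligands having >= 1 activity record at it).
target_panel_set <- function(library, target_id) {
  lids <- unique(library$activities$ligand_id[
    library$activities$target_id == target_id])
  fp_set_subset(library$panels, lids)
}

# Accept a SMILES, molecule tibble or prebuilt panel as the query.
as_query_panel <- function(query, config) {
  if (inherits(query, "fp_set")) {
    if (length(query$ids) != 1L) {
      stop("query panel must hold exactly one molecule", call. = FALSE)
    }
    return(query)
  }
  mol <- if (is.character(query)) parse_smiles(query) else {
    stopifnot(is.data.frame(query))
    if (nrow(query) != 1L) stop("query must be a single molecule", call. = FALSE)
    query
  }
  compute_panels(mol$canonical_smiles, config)
}
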