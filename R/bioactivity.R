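# Nearest-neighbour bioactivity profiling.
#
# Potencies are averaged on the pActivity scale (9 - log10 nM, i.e. the
# negative log-molar potency) because measured potencies are close to
# log-normal. For each target and activity type the neighbours are the
# target's ligands with a curated record of that type whose mean 13-kind
# similarity to the query reaches the admission threshold; the prediction
# is their similarity-weighted mean pActivity and sigma_p the best
# (smallest) weighted variance among the predicted types.

#' Convert a potency in nM to the pActivity scale
#'
#' `pActivity = 9 - log10(value in nM)`; 1 nM maps to 9, 1 uM to 6.
#'
#' @param value_nM Positive potency values in nM.
#' @return pActivity values (unitless).
#' @export
to_p_activity <- function(value_nM) {
  if (any(!is.finite(value_nM) | value_nM <= 0)) {
    stop("potency values must be positive and finite (nM)", call. = FALSE)
  }
  9 - log10(value_nM)
}

#' Convert a pActivity back to nM
#'
#' @param p pActivity values.
#' @return Potency in nM.
#' @export
from_p_activity <- function(p) 10^(9 - p)

#' Bioactivity-profiling parameters
#'
#' @param neighbor_min_similarity Minimum mean 13-kind similarity for a
#'   reference ligand to count as a neighbour (default 0.5).
#' @param weight_power Exponent applied to the mean similarity when
#'   weighting neighbours (default 3; larger sharpens the prediction
#'   toward the nearest neighbours).
#' @param min_neighbors Minimum neighbour count for a prediction
#'   (default 1).
#' @return A `bioactivity_params` list.
#' @export
bioactivity_params <- function(neighbor_min_similarity = 0.5, weight_power = 3,
                               min_neighbors = 1L) {
  stopifnot(neighbor_min_similarity >= 0, neighbor_min_similarity <= 1,
            weight_power > 0, min_neighbors >= 1L)
  structure(
    list(neighbor_min_similarity = neighbor_min_similarity,
         weight_power = weight_power,
         min_neighbors = as.integer(min_neighbors)),
    class = "bioactivity_params")
}

#' Predict one bioactivity value for a query at a target
#'
#' Weighted-nearest-neighbour prediction for one activity type. Each
#' neighbour contributes its best (minimum nM) curated value of that type,
#' weighted by `mean_similarity ^ weight_power`; the prediction is the
#' weighted mean pActivity (reported in nM) and the variance the weighted
#' population variance of neighbour pActivities around it. Each
#' neighbour's tau is its normalized evidence weight `w_i / sum(w)`.
#'
#' @inheritParams fish_targets
#' @param target_id A target present in the library.
#' @param standard_type One of `"IC50"`, `"EC50"`, `"Ki"`, `"Kd"`.
#' @param params [bioactivity_params()].
#' @return `NULL` when no neighbour qualifies; otherwise a list with
#'   `value_nM`, `p_activity`, `variance` (pActivity^2 units) and
#'   `neighbors`, a tibble with `ligand_id`, `mean_similarity`, `tau`,
#'   `standard_type`, `value_nM`, `p_activity`.
#' @export
predict_activity <- function(query, target_id, standard_type, library,
                             params = bioactivity_params()) {
  stopifnot(inherits(library, "reference_library"))
  if (!target_id %in% library$targets$target_id) {
    stop("unknown target_id: ", target_id, call. = FALSE)
  }
  standard_type <- match.arg(standard_type, ACTIVITY_TYPES)
  qp <- as_query_panel(query, library$config)
  tp <- target_panel_set(library, target_id)
  mean_sims <- colMeans(similarity_matrix(qp, tp))
  predict_activity_from_sims(mean_sims, target_id, standard_type, library, params)
}

# Core predictor given precomputed mean similarities for the target's
# ligands (named by ligand_id); shared by predict_activity and
# profile_bioactivity so the panel is computed once per query.
predict_activity_from_sims <- function(mean_sims, target_id, standard_type,
                                       library, params) {
  act <- library$activities
  typed <- act[act$target_id == target_id & act$standard_type == standard_type, ,
               drop = FALSE]
  if (!nrow(typed)) return(NULL)
  lids <- unique(typed$ligand_id)
  sims <- mean_sims[lids]
  keep <- sims >= params$neighbor_min_similarity
  if (sum(keep) < params$min_neighbors) return(NULL)
  lids <- lids[keep]
  sims <- sims[keep]

  value <- vapply(lids, function(l) min(typed$standard_value[typed$ligand_id == l]),
                  numeric(1))
  p <- to_p_activity(value)
  w <- sims^params$weight_power
  if (sum(w) <= 0) return(NULL)
  tau <- w / sum(w)
  p_hat <- sum(tau * p)
  variance <- sum(tau * (p - p_hat)^2)

  neighbors <- tibble::tibble(
    ligand_id = lids,
    mean_similarity = unname(sims),
    tau = unname(tau),
    standard_type = standard_type,
    value_nM = unname(value),
    p_activity = unname(p)
  )
  neighbors <- neighbors[order(-neighbors$mean_similarity, neighbors$ligand_id), ]
  list(value_nM = from_p_activity(p_hat), p_activity = p_hat,
       variance = variance, neighbors = neighbors)
}

#' Bioactivity profile of a query molecule
#'
#' Predicts IC50, EC50, Ki and Kd for every library target with at least
#' one qualifying neighbour of that type. Targets are ranked by ascending
#' sigma_p — the best (smallest) weighted variance among the target's
#' predicted types — with ties broken by descending best neighbour
#' similarity and then target id. Targets with no predictable type are
#' omitted.
#'
#' @inheritParams predict_activity
#' @return A `profile_result` tibble: `rank`, `target_id`, `name`,
#'   `IC50`, `EC50`, `Ki`, `Kd` (predicted nM, `NA` when not predictable),
#'   `sigma_p`, `best_type`, and `neighbors` (list column: one tibble per
#'   predicted type).
#' @export
profile_bioactivity <- function(query, library, params = bioactivity_params()) {
  stopifnot(inherits(library, "reference_library"))
  if (nrow(library$targets) == 0L) {
    stop("reference library holds no targets", call. = FALSE)
  }
  qp <- as_query_panel(query, library$config)

  rows <- purrr::map_dfr(library$targets$target_id, function(tid) {
    tp <- target_panel_set(library, tid)
    mean_sims <- colMeans(similarity_matrix(qp, tp))
    preds <- lapply(stats::setNames(ACTIVITY_TYPES, ACTIVITY_TYPES), function(ty) {
      predict_activity_from_sims(mean_sims, tid, ty, library, params)
    })
    preds <- preds[!vapply(preds, is.null, logical(1))]
    if (!length(preds)) return(NULL)
    variances <- vapply(preds, `[[`, numeric(1), "variance")
    best_type <- names(preds)[which.min(variances)]
    vals <- stats::setNames(rep(NA_real_, 4L), ACTIVITY_TYPES)
    for (ty in names(preds)) vals[[ty]] <- preds[[ty]]$value_nM
    tibble::tibble(
      target_id = tid,
      IC50 = vals[["IC50"]], EC50 = vals[["EC50"]],
      Ki = vals[["Ki"]], Kd = vals[["Kd"]],
      sigma_p = min(variances),
      best_type = best_type,
      best_neighbor_similarity = max(vapply(
        preds, function(p) max(p$neighbors$mean_similarity), numeric(1))),
      neighbors = list(lapply(preds, `[[`, "neighbors"))
    )
  })
  if (is.null(rows) || nrow(rows) == 0L) {
    rows <- tibble::tibble(
      target_id = character(), IC50 = numeric(), EC50 = numeric(),
      Ki = numeric(), Kd = numeric(), sigma_p = numeric(),
      best_type = character(), best_neighbor_similarity = numeric(),
      neighbors = list())
  }
  rows <- dplyr::left_join(rows, library$targets[, c("target_id", "name")],
                           by = "target_id")
  rows <- rows[order(rows$sigma_p, -rows$best_neighbor_similarity,
                     rows$target_id), ]
  out <- rows[, c("target_id", "name", "IC50", "EC50", "Ki", "Kd", "sigma_p",
                  "best_type", "best_neighbor_similarity", "neighbors")]
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1L)
  attr(out, "query_smiles") <- qp$smiles[[1]]
  attr(out, "params") <- params
  class(out) <- c("profile_result", class(out))
  out
}
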