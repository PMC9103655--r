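# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a target-fishing result
#'
#' One row per (target, fingerprint kind) with the best similarity and its
#' over/under-threshold flag, unnesting the per-kind vectors.
#'
#' @param x A `fishing_result`.
#' @param ... Unused.
#' @return A tibble with `rank`, `target_id`, `name`, `score`, `reliable`,
#'   `kind`, `best_similarity`, `over_threshold`.
#' @method tidy fishing_result
#' @export
tidy.fishing_result <- function(x, ...) {
  params <- attr(x, "params")
  kinds <- fingerprint_kinds()
  tbl <- tibble::as_tibble(x)
  purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
    best <- tbl$per_kind_best[[i]]
    tibble::tibble(
      rank = tbl$rank[i], target_id = tbl$target_id[i], name = tbl$name[i],
      score = tbl$score[i], reliable = tbl$reliable[i],
      kind = factor(kinds, levels = kinds),
      best_similarity = unname(best[kinds]),
      over_threshold = unname(best[kinds] >= params$thresholds[kinds])
    )
  })
}

#' One-row summary of a target-fishing result
#'
#' @param x A `fishing_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_targets_reported`, `n_reliable`,
#'   `top_score`, `top_target`, `query_smiles`.
#' @method glance fishing_result
#' @export
glance.fishing_result <- function(x, ...) {
  tibble::tibble(
    n_targets_reported = nrow(x),
    n_reliable = sum(x$reliable),
    top_score = if (nrow(x)) x$score[[1]] else NA_integer_,
    top_target = if (nrow(x)) x$target_id[[1]] else NA_character_,
    query_smiles = attr(x, "query_smiles")
  )
}

#' Tidy a bioactivity profile
#'
#' One row per (target, activity type) prediction, with the per-type
#' neighbour count.
#'
#' @param x A `profile_result`.
#' @param ... Unused.
#' @return A tibble with `rank`, `target_id`, `name`, `standard_type`,
#'   `predicted_nM`, `predicted_p_activity`, `sigma_p`, `n_neighbors`.
#' @method tidy profile_result
#' @export
tidy.profile_result <- function(x, ...) {
  tbl <- tibble::as_tibble(x)
  purrr::map_dfr(seq_len(nrow(tbl)), function(i) {
    nb <- tbl$neighbors[[i]]
    purrr::map_dfr(names(nb), function(ty) {
      tibble::tibble(
        rank = tbl$rank[i], target_id = tbl$target_id[i], name = tbl$name[i],
        standard_type = ty,
        predicted_nM = tbl[[ty]][i],
        predicted_p_activity = to_p_activity(tbl[[ty]][i]),
        sigma_p = tbl$sigma_p[i],
        n_neighbors = nrow(nb[[ty]])
      )
    })
  })
}

#' One-row summary of a bioactivity profile
#'
#' @param x A `profile_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_targets_predicted`, `best_sigma_p`,
#'   `top_target`, `query_smiles`.
#' @method glance profile_result
#' @export
glance.profile_result <- function(x, ...) {
  tibble::tibble(
    n_targets_predicted = nrow(x),
    best_sigma_p = if (nrow(x)) x$sigma_p[[1]] else NA_real_,
    top_target = if (nrow(x)) x$target_id[[1]] else NA_character_,
    query_smiles = attr(x, "query_smiles")
  )
}

#' Plot a target-fishing result
#'
#' Consensus scores of the reported targets as a ranked bar chart,
#' coloured by the reliability flag, with the reliability cutoff marked.
#'
#' @param object A `fishing_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fishing_result
#' @export
autoplot.fishing_result <- function(object, ...) {
  params <- attr(object, "params")
  df <- tibble::as_tibble(object)
  df$target <- factor(df$target_id, levels = rev(df$target_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, y = .data$target,
                                   fill = .data$reliable)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = params$reliability_min_score - 0.5,
                        linetype = "dashed") +
    ggplot2::scale_x_continuous(limits = c(0, 13.5),
                                breaks = seq(0, 13, 2)) +
    ggplot2::labs(x = "consensus score (fingerprint kinds over threshold)",
                  y = NULL, fill = "reliable",
                  title = "Fished targets",
                  subtitle = attr(object, "query_smiles")) +
    ggplot2::theme_minimal()
}

#' Plot a bioactivity profile
#'
#' Predicted potencies per activity type against the per-target sigma_p.
#'
#' @param object A `profile_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot profile_result
#' @export
autoplot.profile_result <- function(object, ...) {
  df <- tidy.profile_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted_p_activity,
                                   y = .data$sigma_p,
                                   colour = .data$standard_type,
                                   label = .data$target_id)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "predicted pActivity", y = "sigma_p (pActivity^2)",
                  colour = "type", title = "Bioactivity profile",
                  subtitle = attr(object, "query_smiles")) +
    ggplot2::theme_minimal()
}

#' Plot the 13-kind similarity evidence for one target
#'
#' Heatmap of per-kind Tanimoto similarities for the most similar
#' reference ligands, the package's rendering of the per-fingerprint
#' over/under-threshold evidence.
#'
#' @param evidence A tibble from [similarity_analysis()].
#' @param thresholds Optional per-kind thresholds to mark over-threshold
#'   cells.
#' @return A ggplot object.
#' @export
plot_similarity_evidence <- function(evidence, thresholds = NULL) {
  kinds <- fingerprint_kinds()
  df <- purrr::map_dfr(seq_len(nrow(evidence)), function(i) {
    tibble::tibble(
      ligand_id = evidence$ligand_id[[i]],
      kind = factor(kinds, levels = kinds),
      similarity = unname(evidence$similarities[[i]][kinds]),
      over = unname(evidence$over_threshold[[i]][kinds])
    )
  })
  df$ligand_id <- factor(df$ligand_id, levels = rev(evidence$ligand_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$kind, y = .data$ligand_id,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$over, , drop = FALSE], size = 1,
                        colour = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tanimoto",
                  title = "Similarity evidence (dot = over threshold)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
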