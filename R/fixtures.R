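# Synthetic reference data with the statistical structure the similarity
# principle assumes: each target owns a congeneric ligand series (one
# scaffold, enumerated substituents) so intra-target fingerprint
# similarity is high and cross-target similarity low, and activities are
# log-normal around a target-specific potency.

#' Default scaffold pool for synthetic fixtures
#'
#' 48 distinct ring systems: 16 base rings, their phenyl-linked analogues
#' and their anilide-linked analogues. Every entry is a valid SMILES that
#' remains valid when prefixed with a substituent chain, which is how the
#' generator grows a congeneric series from a scaffold.
#'
#' @return Character vector of 48 scaffold SMILES.
#' @export
default_scaffold_pool <- function() {
  base <- c(
    "c1ccccc1", "c1ccncc1", "c1cnccn1", "c1ccc2ccccc2c1",
    "c1ccc2ncccc2c1", "c1ccc2[nH]ccc2c1", "c1ccc2occc2c1", "c1ccc2sccc2c1",
    "c1cc[nH]c1", "c1ccoc1", "c1ccsc1", "c1cnc[nH]1",
    "C1CCCCC1", "C1CCNCC1", "C1CCOCC1", "C1CCCC1"
  )
  shifted <- vapply(base, function(s) gsub("1", "2", s, fixed = TRUE), character(1))
  phenyl <- paste0("c1ccc(-", shifted, ")cc1")
  anilide <- paste0("C(=O)N", base)
  unname(c(base, phenyl, anilide))
}

# Substituent chains used to decorate a scaffold into a series. Each is a
# valid SMILES prefix whose last atom bonds to the scaffold's first atom.
FIXTURE_SUBSTITUENTS <- c(
  "C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC",
  "CC(C)", "CC(C)C", "OC", "OCC", "OCCC", "NC",
  "NCC", "CN(C)", "COC", "CCOCC"
)

#' Specification of a synthetic reference fixture
#'
#' @param seed Integer seed; all fixture randomness flows from it.
#' @param n_targets Number of protein targets.
#' @param ligands_per_target Ligands in each target's congeneric series.
#' @param scaffold_pool Candidate scaffolds (must parse; one per target).
#' @param activity_log_mean_range pActivity interval from which each
#'   target's true mean potency is drawn (default 6-9, i.e. 1 uM to 1 nM).
#' @param activity_log_sd Within-series noise sd in pActivity units
#'   (default 0.3).
#' @param fraction_malformed Fraction of deliberately malformed activity
#'   records added on top of the well-formed ones, each violating exactly
#'   one curation rule (default 0).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_targets = 8L, ligands_per_target = 5L,
                         scaffold_pool = default_scaffold_pool(),
                         activity_log_mean_range = c(6, 9),
                         activity_log_sd = 0.3,
                         fraction_malformed = 0) {
  stopifnot(length(scaffold_pool) >= n_targets,
            ligands_per_target >= 1L,
            ligands_per_target <= length(FIXTURE_SUBSTITUENTS),
            activity_log_sd >= 0,
            fraction_malformed >= 0, fraction_malformed <= 1,
            diff(range(activity_log_mean_range)) >= 0)
  structure(
    list(seed = as.integer(seed), n_targets = as.integer(n_targets),
         ligands_per_target = as.integer(ligands_per_target),
         scaffold_pool = scaffold_pool,
         activity_log_mean_range = as.numeric(activity_log_mean_range),
         activity_log_sd = activity_log_sd,
         fraction_malformed = fraction_malformed),
    class = "fixture_spec")
}

MALFORMED_KINDS <- c("relation", "units", "confidence", "comment", "prodrug",
                     "target_type")

#' Generate raw reference tables from a fixture spec
#'
#' Deterministically (per seed) builds ChEMBL-style raw tables: each
#' target gets a distinct scaffold and a congeneric ligand series
#' (scaffold plus enumerated substituents); one activity record per
#' ligand, drawn log-normally around the target's true pActivity with the
#' spec's noise sd, types cycling through IC50/EC50/Ki/Kd, emitted in nM.
#' A documented quota of malformed records each violates exactly one
#' curation rule (relation ">", units "uM", confidence 3, comment
#' "inactive", prodrug-flagged ligand, non-protein target).
#'
#' @param spec A [fixture_spec()].
#' @return A list with raw `targets`, `ligands`, `activities` tibbles,
#'   `truth` (per-target scaffold and true mean pActivity),
#'   `malformed_quota` (tibble rule/n), and the spec.
#' @export
generate_reference_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  bad <- is.na(suppressMessages(canonicalize_smiles(spec$scaffold_pool)))
  if (any(bad)) {
    stop("invalid SMILES in scaffold pool: ",
         paste(spec$scaffold_pool[bad], collapse = ", "), call. = FALSE)
  }
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  n_t <- spec$n_targets
  scaffolds <- spec$scaffold_pool[sample.int(length(spec$scaffold_pool), n_t)]
  mu <- stats::runif(n_t, spec$activity_log_mean_range[1],
                     spec$activity_log_mean_range[2])

  targets <- tibble::tibble(
    target_id = sprintf("T%03d", seq_len(n_t)),
    name = sprintf("Synthetic protein %03d", seq_len(n_t)),
    target_type = rep(c("Single protein", "Protein complex"),
                      length.out = n_t),
    organism = rep(c("Homo sapiens", "Rattus norvegicus", "Mus musculus"),
                   length.out = n_t)
  )

  lig_rows <- list(); act_rows <- list()
  for (i in seq_len(n_t)) {
    subs <- FIXTURE_SUBSTITUENTS[seq_len(spec$ligands_per_target)]
    smiles <- paste0(subs, scaffolds[i])
    ids <- sprintf("L%03d_%02d", i, seq_along(smiles))
    lig_rows[[i]] <- tibble::tibble(
      ligand_id = ids, canonical_smiles = smiles,
      molecule_type = "Small_molecule", prodrug_flag = 0L)
    p_act <- mu[i] + stats::rnorm(length(ids), 0, spec$activity_log_sd)
    act_rows[[i]] <- tibble::tibble(
      ligand_id = ids,
      target_id = targets$target_id[i],
      standard_type = ACTIVITY_TYPES[((seq_along(ids) - 1L) %% 4L) + 1L],
      standard_relation = "=",
      standard_units = "nM",
      standard_value = from_p_activity(p_act),
      confidence_score = 8L,
      activity_comment = NA_character_
    )
  }
  ligands <- dplyr::bind_rows(lig_rows)
  activities <- dplyr::bind_rows(act_rows)

  n_good <- nrow(activities)
  n_mal <- round(spec$fraction_malformed * n_good)
  quota <- stats::setNames(integer(length(MALFORMED_KINDS)), MALFORMED_KINDS)
  if (n_mal > 0) {
    mal_acts <- list()
    extra_ligs <- list(); extra_targs <- list()
    for (m in seq_len(n_mal)) {
      kind <- MALFORMED_KINDS[((m - 1L) %% length(MALFORMED_KINDS)) + 1L]
      quota[[kind]] <- quota[[kind]] + 1L
      t_i <- ((m - 1L) %% n_t) + 1L
      base_rec <- tibble::tibble(
        ligand_id = ligands$ligand_id[[((m - 1L) %% nrow(ligands)) + 1L]],
        target_id = targets$target_id[[t_i]],
        standard_type = ACTIVITY_TYPES[((m - 1L) %% 4L) + 1L],
        standard_relation = "=", standard_units = "nM",
        standard_value = from_p_activity(mu[t_i]),
        confidence_score = 8L, activity_comment = NA_character_)
      if (kind == "relation") base_rec$standard_relation <- ">"
      if (kind == "units") base_rec$standard_units <- "uM"
      if (kind == "confidence") base_rec$confidence_score <- 3L
      if (kind == "comment") base_rec$activity_comment <- "inactive"
      if (kind == "prodrug") {
        pid <- sprintf("LBAD%03d", m)
        extra_ligs[[length(extra_ligs) + 1L]] <- tibble::tibble(
          ligand_id = pid, canonical_smiles = "CCOC(=O)c1ccccc1",
          molecule_type = "Small_molecule", prodrug_flag = 1L)
        base_rec$ligand_id <- pid
      }
      if (kind == "target_type") {
        tid <- sprintf("TBAD%03d", m)
        extra_targs[[length(extra_targs) + 1L]] <- tibble::tibble(
          target_id = tid, name = sprintf("Whole organism %03d", m),
          target_type = "Organism", organism = "Homo sapiens")
        base_rec$target_id <- tid
      }
      mal_acts[[m]] <- base_rec
    }
    ligands <- dplyr::bind_rows(ligands, extra_ligs)
    targets <- dplyr::bind_rows(targets, extra_targs)
    activities <- dplyr::bind_rows(activities, mal_acts)
  }

  list(
    targets = targets, ligands = ligands, activities = activities,
    truth = tibble::tibble(target_id = sprintf("T%03d", seq_len(n_t)),
                           scaffold = scaffolds, mu_p_activity = mu),
    malformed_quota = tibble::tibble(rule = MALFORMED_KINDS,
                                     n = unname(quota)),
    spec = spec
  )
}

#' Held-out query molecules from a fixture's series
#'
#' Builds in-series molecules that are not part of the library: the same
#' scaffolds decorated with substituents beyond those used for the
#' library ligands. Used for parameter-recovery checks.
#'
#' @param fixture A fixture from [generate_reference_fixture()].
#' @param n_per_target Held-out molecules per target.
#' @return A tibble: `target_id`, `canonical_smiles`, `mu_p_activity`.
#' @export
fixture_heldout_queries <- function(fixture, n_per_target = 1L) {
  spec <- fixture$spec
  avail <- length(FIXTURE_SUBSTITUENTS) - spec$ligands_per_target
  stopifnot(n_per_target >= 1L, n_per_target <= avail)
  subs <- FIXTURE_SUBSTITUENTS[spec$ligands_per_target + seq_len(n_per_target)]
  purrr::map_dfr(seq_len(nrow(fixture$truth)), function(i) {
    tibble::tibble(
      target_id = fixture$truth$target_id[i],
      canonical_smiles = paste0(subs, fixture$truth$scaffold[i]),
      mu_p_activity = fixture$truth$mu_p_activity[i]
    )
  })
}

#' Intra- vs inter-target similarity separation of a fixture
#'
#' Computes the mean of mean-13-kind Tanimoto similarities between ligand
#' pairs of the same target (intra) and between ligands of different
#' targets (inter). Congeneric series are designed so intra clearly
#' exceeds inter; a single-target fixture has no inter pairs (`NA`).
#'
#' @param fixture A fixture from [generate_reference_fixture()].
#' @param config Fingerprint configuration.
#' @return A list with `intra` and `inter` mean similarities.
#' @export
intra_inter_similarity_check <- function(fixture,
                                         config = default_fingerprint_config()) {
  good <- fixture$ligands[fixture$ligands$prodrug_flag != 1L, , drop = FALSE]
  fps <- compute_panels(good$canonical_smiles, config, ids = good$ligand_id)
  tgt <- fixture$activities$target_id[match(good$ligand_id,
                                            fixture$activities$ligand_id)]
  n <- length(fps$ids)
  mean_sim <- matrix(0, n, n)
  for (i in seq_len(n)) {
    mean_sim[i, ] <- colMeans(similarity_matrix(fps, fps, i))
  }
  same <- outer(tgt, tgt, `==`)
  diag(same) <- NA
  pairs <- upper.tri(mean_sim)
  intra_vals <- mean_sim[pairs & !is.na(same) & same]
  inter_vals <- mean_sim[pairs & !is.na(same) & !same]
  list(intra = if (length(intra_vals)) mean(intra_vals) else NA_real_,
       inter = if (length(inter_vals)) mean(inter_vals) else NA_real_)
}
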