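# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, .fixture_cache)) {
    assign(key, builder(), .fixture_cache)
  }
  get(key, .fixture_cache)
}

# The standard synthetic fixture: 8 targets x 5 ligands, 15% malformed.
standard_fixture <- function() {
  cached("standard_fixture", function() {
    generate_reference_fixture(
      fixture_spec(seed = 101L, n_targets = 8L, ligands_per_target = 5L,
                   fraction_malformed = 0.15))
  })
}

standard_library <- function() {
  cached("standard_library", function() {
    fx <- standard_fixture()
    cur <- filter_activity_records(fx$targets, fx$ligands, fx$activities)
    build_reference_library(cur, timestamp = "fixed-for-tests")
  })
}

# Query panel of a library ligand, reusing the precomputed panel.
library_ligand_panel <- function(lib, ligand_id) {
  ligfish:::fp_set_subset(lib$panels, ligand_id)
}

# A tiny hand-built bit-vector world for exact Tanimoto / scoring oracles:
# every kind is 64 bits and panels are set directly, no chemistry.
manual_config <- function(nbits = 64L) {
  kinds <- fingerprint_kinds()
  cfg <- lapply(kinds, function(k) list(backend = "manual", nbits = nbits,
                                        params = list()))
  names(cfg) <- kinds
  cfg
}

# panels: named list ligand_id -> either a single integer vector of on-bits
# (used for all 13 kinds) or a list kind -> on-bits.
make_manual_fpset <- function(panels, nbits = 64L) {
  kinds <- fingerprint_kinds()
  ids <- names(panels)
  bits <- list(); n_on <- list()
  for (k in kinds) {
    cols <- lapply(panels, function(p) {
      on <- if (is.list(p)) p[[k]] else p
      b <- integer(nbits)
      if (length(on)) b[on] <- 1L
      b
    })
    packed <- vapply(cols, ligfish:::pack_bits, raw(nbits / 8L))
    bits[[k]] <- matrix(packed, nrow = nbits / 8L, ncol = length(ids))
    n_on[[k]] <- vapply(cols, function(b) sum(b), integer(1))
  }
  structure(
    list(ids = ids, smiles = ids, kinds = kinds,
         nbits = stats::setNames(rep(as.integer(nbits), length(kinds)), kinds),
         bits = bits, n_on = n_on, config = manual_config(nbits)),
    class = "fp_set")
}

# A reference_library assembled from manual panels and explicit activity
# records; targets/ligands tables are derived.
make_manual_library <- function(panels, activities, nbits = 64L) {
  fps <- make_manual_fpset(panels, nbits)
  ligands <- tibble::tibble(
    ligand_id = fps$ids, canonical_smiles = fps$ids,
    molecule_type = "Small_molecule", prodrug_flag = 0L)
  tids <- unique(activities$target_id)
  targets <- tibble::tibble(
    target_id = tids, name = paste("Manual target", tids),
    target_type = "Single protein", organism = "Homo sapiens")
  structure(
    list(targets = targets, ligands = ligands,
         activities = tibble::as_tibble(activities),
         panels = fps, config = fps$config,
         metadata = list(source_name = "manual", source_version = "0",
                         built = "fixed", n_targets = nrow(targets),
                         n_ligands = nrow(ligands),
                         n_activities = nrow(activities),
                         dropped_ligands = tibble::tibble(
                           ligand_id = character(), reason = character()),
                         filter_rules = ligfish:::FILTER_RULES)),
    class = "reference_library")
}

activity_row <- function(ligand_id, target_id, type = "IC50", value = 100,
                         relation = "=", units = "nM", confidence = 8L,
                         comment = NA_character_) {
  tibble::tibble(
    ligand_id = ligand_id, target_id = target_id, standard_type = type,
    standard_relation = relation, standard_units = units,
    standard_value = value, confidence_score = confidence,
    activity_comment = comment)
}

# Set-based brute-force Tanimoto oracle over explicit bit positions.
tanimoto_oracle <- function(on_a, on_b) {
  if (!length(union(on_a, on_b))) return(0)
  length(intersect(on_a, on_b)) / length(union(on_a, on_b))
}
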