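# Fingerprint panel API: 13 binary 2D fingerprint kinds in a fixed
# declaration order, packed-bit storage, popcount Tanimoto.

#' The 13 fingerprint kinds of the panel
#'
#' Returns the names of the 13 fingerprint kinds in their canonical panel
#' order. Every similarity profile, threshold vector and consensus score in
#' the package iterates kinds in exactly this order.
#'
#' @return A character vector of length 13.
#' @export
fingerprint_kinds <- function() {
  c("pubchem", "graph", "pattern", "substructure", "cdk_maccs", "featmfp1",
    "fp2", "rdkit7", "klekota_roth", "hybridization", "mfp1", "ap_bits",
    "tt_bits")
}

#' Default fingerprint configuration
#'
#' One backend descriptor per kind: the generator, its bit length and its
#' parameters. Kinds without a native generator in the installed toolkits
#' (OpenBabel, ChemmineR atom pairs) are computed from the heavy-atom
#' graph by the package's own hashed-path, torsion and count-key
#' generators; each slot is an independent 2D fingerprint and the defaults
#' here are frozen by golden-file tests.
#'
#' @return A named list (one entry per kind, canonical order) with fields
#'   `backend`, `nbits`, and backend-specific `params`.
#' @export
default_fingerprint_config <- function() {
  cfg <- list(
    pubchem       = list(backend = "count_keys", nbits = 128L, params = list()),
    graph         = list(backend = "path_hash", nbits = 1024L,
                         params = list(max_atoms = 6L, invariant = "element",
                                       use_bond_order = FALSE)),
    pattern       = list(backend = "openbabel", nbits = 512L, params = list(name = "FP4")),
    substructure  = list(backend = "openbabel", nbits = 64L, params = list(name = "FP3")),
    cdk_maccs     = list(backend = "openbabel", nbits = 256L, params = list(name = "MACCS")),
    featmfp1      = list(backend = "openbabel", nbits = 4096L, params = list(name = "ECFP4")),
    fp2           = list(backend = "openbabel", nbits = 1024L, params = list(name = "FP2")),
    rdkit7        = list(backend = "path_hash", nbits = 2048L,
                         params = list(max_atoms = 7L, invariant = "element",
                                       use_bond_order = TRUE)),
    klekota_roth  = list(backend = "smarts_keys", nbits = 48L, params = list()),
    hybridization = list(backend = "path_hash", nbits = 1024L,
                         params = list(max_atoms = 6L, invariant = "hybridization",
                                       use_bond_order = FALSE)),
    mfp1          = list(backend = "openbabel", nbits = 4096L, params = list(name = "ECFP2")),
    ap_bits       = list(backend = "chemminer_ap", nbits = 1024L, params = list()),
    tt_bits       = list(backend = "torsion_hash", nbits = 2048L, params = list())
  )
  stopifnot(identical(names(cfg), fingerprint_kinds()))
  cfg
}

#' Compute fingerprint panels for a batch of molecules
#'
#' Computes the full 13-kind fingerprint panel for each molecule. The
#' computation is deterministic: the same canonical SMILES under the same
#' configuration yields a bit-identical panel. A backend failure for any
#' kind is a hard error naming the kind — a panel is never partial.
#'
#' @param molecules A molecule tibble (from [parse_smiles()] /
#'   [read_molecules()]), or a character vector of SMILES.
#' @param config A fingerprint configuration, see
#'   [default_fingerprint_config()].
#' @param ids Optional ids for the panels; defaults to molecule names when
#'   present, otherwise the canonical SMILES.
#' @return An `fp_set`: panels for all molecules, packed-bit storage.
#' @export
compute_panels <- function(molecules, config = default_fingerprint_config(),
                           ids = NULL) {
  smiles <- molecule_smiles(molecules)
  if (!length(smiles)) stop("no molecules to fingerprint", call. = FALSE)
  if (any(is.na(smiles) | !nzchar(smiles))) {
    stop("invalid structure among fingerprint inputs", call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- if (is.data.frame(molecules) && "name" %in% names(molecules) &&
               !anyNA(molecules$name)) molecules$name else smiles
  }
  stopifnot(length(ids) == length(smiles), !anyNA(ids))

  kinds <- names(config)
  ob_kinds <- purrr::keep(config, ~ .x$backend == "openbabel")
  ob_names <- vapply(ob_kinds, function(k) k$params$name, character(1))

  ob_feats <- tryCatch(
    ob_batch_features(smiles, ob_names, SMARTS_KEYS),
    error = function(e) stop("panel build failed in backend 'openbabel': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(ob_feats) != length(smiles)) {
    stop("panel build failed: OpenBabel parsed ", length(ob_feats),
         " of ", length(smiles), " molecules", call. = FALSE)
  }

  sdf <- tryCatch(
    ChemmineR::smiles2sdf(stats::setNames(smiles, paste0("M", seq_along(smiles)))),
    error = function(e) stop("panel build failed in backend 'graph': ",
                             conditionMessage(e), call. = FALSE)
  )
  graphs <- lapply(seq_along(smiles), function(i) mol_graph_from_sdf(sdf[[i]]))

  ap_cfg <- config[["ap_bits"]]
  ap_bits_m <- NULL
  if (!is.null(ap_cfg) && ap_cfg$backend == "chemminer_ap") {
    ap_bits_m <- tryCatch({
      apset <- ChemmineR::sdf2ap(sdf)
      suppressWarnings(ChemmineR::desc2fp(apset, descnames = ap_descriptor_names(ap_cfg$nbits),
                                          type = "matrix"))
    }, error = function(e) stop("panel build failed in backend 'chemminer_ap': ",
                                conditionMessage(e), call. = FALSE))
  }

  n <- length(smiles)
  bits <- vector("list", length(kinds))
  names(bits) <- kinds
  n_on <- vector("list", length(kinds))
  names(n_on) <- kinds

  for (kind in kinds) {
    kc <- config[[kind]]
    rows <- switch(kc$backend,
      openbabel = lapply(ob_feats, function(f) f$ob[[kind]]),
      smarts_keys = lapply(ob_feats, function(f) f$smarts),
      path_hash = lapply(graphs, function(g) {
        fp_path_hash(g, kc$nbits, kc$params$max_atoms, kc$params$invariant,
                     kc$params$use_bond_order)
      }),
      torsion_hash = lapply(graphs, function(g) fp_torsion_hash(g, kc$nbits)),
      count_keys = lapply(graphs, function(g) fp_count_keys(g, kc$nbits)),
      chemminer_ap = lapply(seq_len(n), function(i) as.integer(ap_bits_m[i, ])),
      stop("panel build failed: unknown backend ", sQuote(kc$backend),
           " for kind ", sQuote(kind), call. = FALSE)
    )
    bad <- which(lengths(rows) != kc$nbits)
    if (length(bad)) {
      stop("panel build failed for kind ", sQuote(kind), ": backend returned ",
           length(rows[[bad[1]]]), " bits, expected ", kc$nbits, call. = FALSE)
    }
    packed <- vapply(rows, pack_bits, raw(kc$nbits / 8L))
    bits[[kind]] <- matrix(packed, nrow = kc$nbits / 8L, ncol = n)
    n_on[[kind]] <- vapply(rows, function(b) sum(b > 0L), integer(1))
  }

  structure(
    list(ids = as.character(ids), smiles = smiles, kinds = kinds,
         nbits = vapply(config, function(k) as.integer(k$nbits), integer(1)),
         bits = bits, n_on = n_on, config = config),
    class = "fp_set"
  )
}

#' Compute the fingerprint panel of a single molecule
#'
#' @inheritParams compute_panels
#' @param molecule A one-row molecule tibble or a single SMILES string.
#' @return An `fp_set` holding exactly one panel.
#' @export
compute_panel <- function(molecule, config = default_fingerprint_config()) {
  smiles <- molecule_smiles(molecule)
  if (length(smiles) != 1L) {
    stop("compute_panel() expects exactly one molecule", call. = FALSE)
  }
  compute_panels(molecule, config)
}

# The reference atom-pair descriptor vocabulary shipped with ChemmineR
# (most frequent pairs); loaded once per session.
ap_names_cache <- new.env(parent = emptyenv())

ap_descriptor_names <- function(nbits) {
  key <- as.character(nbits)
  if (!exists(key, ap_names_cache)) {
    e <- new.env(parent = emptyenv())
    utils::data("apfp", package = "ChemmineR", envir = e)
    assign(key, utils::head(as.character(e$apfp$AP), nbits), ap_names_cache)
  }
  get(key, ap_names_cache)
}

molecule_smiles <- function(molecules) {
  if (is.data.frame(molecules)) {
    if (!"canonical_smiles" %in% names(molecules)) {
      stop("molecule table lacks a canonical_smiles column", call. = FALSE)
    }
    molecules$canonical_smiles
  } else {
    as.character(molecules)
  }
}

#' @export
print.fp_set <- function(x, ...) {
  cat("<fp_set> ", length(x$ids), " molecule(s), ", length(x$kinds),
      " fingerprint kinds (", sum(x$nbits), " bits per panel)\n", sep = "")
  invisible(x)
}

#' Extract one fingerprint from an fp_set
#'
#' @param panel An `fp_set`.
#' @param kind A fingerprint kind name.
#' @param i Panel index (default 1).
#' @return A `fingerprint` object with fields `kind`, `nbits`, `bytes`
#'   (packed bits) and `n_on`.
#' @export
panel_fingerprint <- function(panel, kind, i = 1L) {
  stopifnot(inherits(panel, "fp_set"), kind %in% panel$kinds,
            i >= 1L, i <= length(panel$ids))
  structure(
    list(kind = kind, nbits = panel$nbits[[kind]],
         bytes = panel$bits[[kind]][, i], n_on = panel$n_on[[kind]][i]),
    class = "fingerprint"
  )
}

#' Build a fingerprint from explicit on-bit positions
#'
#' Mainly for toy examples and exact-oracle tests: the fingerprint contains
#' exactly the 1-based bit positions given.
#'
#' @param on_bits Integer vector of 1-based set-bit positions (may be empty).
#' @param nbits Total bit length.
#' @param kind Kind label (defaults to `"manual"`).
#' @return A `fingerprint` object.
#' @export
make_fingerprint <- function(on_bits, nbits, kind = "manual") {
  stopifnot(nbits %% 8L == 0L, all(on_bits >= 1L), all(on_bits <= nbits))
  bits <- integer(nbits)
  bits[on_bits] <- 1L
  structure(
    list(kind = kind, nbits = as.integer(nbits), bytes = pack_bits(bits),
         n_on = length(unique(on_bits))),
    class = "fingerprint"
  )
}

#' Tanimoto similarity of two fingerprints
#'
#' \eqn{T(a,b) = |a \wedge b| / |a \vee b|} over the set bits. Both
#' fingerprints must be of the same kind (and hence length). Two all-zero
#' fingerprints have similarity 0, not 1: a featureless pair is no evidence
#' of similarity.
#'
#' @param a,b `fingerprint` objects of the same kind.
#' @return A similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (!identical(a$kind, b$kind)) {
    stop("fingerprint kind mismatch: ", a$kind, " vs ", b$kind, call. = FALSE)
  }
  inter <- popcount_raw(a$bytes & b$bytes)
  union <- a$n_on + b$n_on - inter
  if (union == 0L) return(0)
  inter / union
}

#' Similarity profile between two panels
#'
#' The 13 per-kind Tanimoto similarities between a query panel and one
#' reference panel, in canonical kind order.
#'
#' @param query,ref `fp_set` objects holding one panel each (or indices
#'   `i`, `j` selecting a panel from larger sets).
#' @param i,j Panel indices into `query` and `ref`.
#' @return A named numeric vector of length 13, values in `[0, 1]`.
#' @export
similarity_profile <- function(query, ref, i = 1L, j = 1L) {
  check_same_kinds(query, ref)
  vapply(query$kinds, function(k) {
    tanimoto(panel_fingerprint(query, k, i), panel_fingerprint(ref, k, j))
  }, numeric(1))
}

# 13 x n matrix of similarities between one query panel and every panel in
# a reference set. Vectorized per kind: AND the query bytes against the
# packed reference matrix and popcount column-wise.
similarity_matrix <- function(query, ref, i = 1L) {
  check_same_kinds(query, ref)
  n <- length(ref$ids)
  out <- matrix(0, nrow = length(ref$kinds), ncol = n,
                dimnames = list(ref$kinds, ref$ids))
  for (k in ref$kinds) {
    q <- query$bits[[k]][, i]
    m <- ref$bits[[k]]
    inter_bytes <- m & as.vector(q)
    inter <- colSums(matrix(POPCOUNT8[as.integer(inter_bytes) + 1L],
                            nrow = nrow(m), ncol = n))
    union <- query$n_on[[k]][i] + ref$n_on[[k]] - inter
    sim <- ifelse(union == 0, 0, inter / union)
    out[k, ] <- sim
  }
  out
}

check_same_kinds <- function(a, b) {
  stopifnot(inherits(a, "fp_set"), inherits(b, "fp_set"))
  if (!identical(a$kinds, b$kinds) || !identical(a$nbits, b$nbits)) {
    stop("fingerprint panels were built under different configurations",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Subset an fp_set by id or index, preserving config.
fp_set_subset <- function(fps, idx) {
  if (is.character(idx)) idx <- match(idx, fps$ids)
  stopifnot(!anyNA(idx))
  structure(
    list(ids = fps$ids[idx], smiles = fps$smiles[idx], kinds = fps$kinds,
         nbits = fps$nbits,
         bits = lapply(fps$bits, function(m) m[, idx, drop = FALSE]),
         n_on = lapply(fps$n_on, function(v) v[idx]),
         config = fps$config),
    class = "fp_set"
  )
}
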