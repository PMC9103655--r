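# Fingerprint backends.
#
# Seven of the 13 panel slots are computed by OpenBabel (via ChemmineOB),
# one by ChemmineR's atom-pair implementation, and five from the molecular
# graph directly (hashed linear-path, topological-torsion and
# count-threshold key fingerprints), because no installed toolkit exposes
# those historical kinds. All custom backends are deterministic functions
# of the kekulized heavy-atom graph.

# -- popcount ----------------------------------------------------------------

POPCOUNT8 <- vapply(0:255, function(x) sum(bitwAnd(bitwShiftR(x, 0:7), 1L)), integer(1))

popcount_raw <- function(r) sum(POPCOUNT8[as.integer(r) + 1L])

pack_bits <- function(bits) packBits(as.integer(bits) > 0L, type = "raw")

# -- OpenBabel word-level fingerprints ---------------------------------------

# OBFingerprint_GetFingerprint returns the fingerprint as a vector of
# 32-bit words coerced to R integers; INT_MIN comes back as NA. Decoding
# the words directly is bit-exact with OBFingerprint_GetBit (bit i lives
# in word i %/% 32 at position i %% 32) and avoids an O(nbits) R loop.
ob_words_to_bits <- function(w) {
  w <- as.numeric(w)
  w[is.na(w)] <- -2^31
  w[w < 0] <- w[w < 0] + 2^32
  as.vector(t(outer(w, 2^(0:31), function(a, b) floor(a / b) %% 2)))
}

# One pass over a batch of molecules computing every OpenBabel-backed kind
# plus the SMARTS key counts. Returns a list per molecule.
ob_batch_features <- function(smiles, ob_kinds, smarts_patterns) {
  handles <- lapply(ob_kinds, ChemmineOB:::OBFingerprint_FindFingerprint)
  names(handles) <- names(ob_kinds)
  smitxt <- paste0(paste(smiles, collapse = "\n"), "\n")
  ChemmineOB::forEachMol("SMI", smitxt, function(mol) {
    fps <- lapply(handles, function(h) {
      w <- ChemmineOB:::OBFingerprint_GetFingerprint(h, mol, numeric(1))[[2]]
      ob_words_to_bits(w)
    })
    keys <- vapply(smarts_patterns, function(p) {
      ChemmineOB::smartsSearch_OB(list(mol), p, uniqueMatches = TRUE) > 0
    }, logical(1))
    list(ob = fps, smarts = as.integer(keys))
  })
}

# -- molecular graph ---------------------------------------------------------

# Heavy-atom graph from a ChemmineR SDF record: element symbols, bond list
# with kekulized orders, adjacency, degree and pi-bond counts.
mol_graph_from_sdf <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    bonds <- matrix(integer(0), ncol = 3)
  } else {
    bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  adj <- vector("list", n)
  bond_order <- vector("list", n)
  if (nrow(bonds)) {
    for (k in seq_len(nrow(bonds))) {
      a <- bonds[k, 1]; b <- bonds[k, 2]; o <- bonds[k, 3]
      adj[[a]] <- c(adj[[a]], b); bond_order[[a]] <- c(bond_order[[a]], o)
      adj[[b]] <- c(adj[[b]], a); bond_order[[b]] <- c(bond_order[[b]], o)
    }
  }
  degree <- vapply(seq_len(n), function(i) length(adj[[i]]), integer(1))
  npi <- vapply(seq_len(n), function(i) sum(bond_order[[i]] > 1L), integer(1))
  list(elements = elements, n = n, bonds = bonds, adj = adj,
       bond_order = bond_order, degree = degree, npi = npi)
}

ELEMENT_CODES <- c(C = 1L, N = 2L, O = 3L, S = 4L, P = 5L, F = 6L, Cl = 7L,
                   Br = 8L, I = 9L, B = 10L, Si = 11L, Se = 12L, H = 13L)

element_code <- function(el) {
  code <- ELEMENT_CODES[el]
  code[is.na(code)] <- 14L
  unname(code)
}

# Approximate hybridization from pi-bond count: 3 = sp3, 2 = sp2, 1 = sp.
hybridization_state <- function(g) {
  has_triple <- vapply(seq_len(g$n), function(i) any(g$bond_order[[i]] >= 3L), logical(1))
  ifelse(has_triple, 1L, ifelse(g$npi > 0L, 2L, 3L))
}

# -- simple-path enumeration -------------------------------------------------

# All simple paths with 1..max_atoms atoms, each undirected path reported
# once (paths of >1 atom are kept when start index < end index).
enumerate_paths <- function(g, max_atoms) {
  paths <- list()
  np <- 0L
  for (start in seq_len(g$n)) {
    stack <- list(start)
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      last <- p[length(p)]
      if (length(p) == 1L || p[1] < last) {
        np <- np + 1L
        paths[[np]] <- p
      }
      if (length(p) < max_atoms) {
        for (nb in g$adj[[last]]) {
          if (!(nb %in% p)) stack[[length(stack) + 1L]] <- c(p, nb)
        }
      }
    }
  }
  paths
}

lookup_order <- function(g, a, b) {
  idx <- match(b, g$adj[[a]])
  g$bond_order[[a]][idx]
}

# Token sequence for a path: atom invariants interleaved with bond tokens,
# direction-canonicalized (lexicographically smaller of the two readings).
path_tokens <- function(g, path, atom_inv, use_bond_order) {
  a <- atom_inv[path]
  if (length(path) == 1L) return(a)
  b <- vapply(seq_len(length(path) - 1L), function(i) {
    if (use_bond_order) lookup_order(g, path[i], path[i + 1L]) else 1L
  }, integer(1))
  fwd <- integer(2L * length(a) - 1L)
  fwd[seq(1L, length(fwd), by = 2L)] <- a
  fwd[seq(2L, length(fwd), by = 2L)] <- b
  rev_ <- rev(fwd)
  for (i in seq_along(fwd)) {
    if (fwd[i] < rev_[i]) return(fwd)
    if (fwd[i] > rev_[i]) return(rev_)
  }
  fwd
}

# Horner-style modular hash of token sequences into a bit vector.
hash_paths_to_bits <- function(token_list, nbits) {
  bits <- integer(nbits)
  if (!length(token_list)) return(bits)
  lens <- lengths(token_list)
  for (L in unique(lens)) {
    m <- do.call(rbind, token_list[lens == L])
    h <- rep(17, nrow(m))
    for (j in seq_len(L)) h <- (h * 31 + m[, j]) %% nbits
    bits[unique(h) + 1L] <- 1L
  }
  bits
}

# Hashed linear-path fingerprint; atom invariants select the kind flavour.
fp_path_hash <- function(g, nbits, max_atoms, invariant = c("element", "hybridization"),
                         use_bond_order = TRUE) {
  invariant <- match.arg(invariant)
  atom_inv <- switch(invariant,
    element = element_code(g$elements) + 4L,
    hybridization = element_code(g$elements) * 4L + hybridization_state(g)
  )
  paths <- enumerate_paths(g, max_atoms)
  toks <- lapply(paths, function(p) path_tokens(g, p, atom_inv, use_bond_order))
  hash_paths_to_bits(toks, nbits)
}

# Topological-torsion fingerprint: hashed 4-atom simple paths with
# (element, degree, pi-count) atom invariants.
fp_torsion_hash <- function(g, nbits) {
  atom_inv <- element_code(g$elements) * 64L + pmin(g$degree, 7L) * 8L + pmin(g$npi, 7L)
  paths <- enumerate_paths(g, 4L)
  paths <- paths[lengths(paths) == 4L]
  toks <- lapply(paths, function(p) path_tokens(g, p, atom_inv, use_bond_order = FALSE))
  hash_paths_to_bits(toks, nbits)
}

# Count-threshold structural keys in the spirit of the classic 881-key
# substructure set, reduced to graph-derivable counts: element counts,
# ring (cyclomatic) counts, bond-order counts and branching counts, each
# at a ladder of thresholds. Fixed 128-bit layout, no hashing.
fp_count_keys <- function(g, nbits = 128L) {
  bits <- integer(nbits)
  slot <- 0L
  set_ladder <- function(count, thresholds) {
    for (t in thresholds) {
      slot <<- slot + 1L
      if (count >= t) bits[slot] <<- 1L
    }
  }
  for (el in c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B")) {
    set_ladder(sum(g$elements == el), c(1, 2, 4, 8, 16, 24, 32))
  }
  n_comp <- graph_components(g)
  cyclomatic <- nrow(g$bonds) - g$n + n_comp
  set_ladder(cyclomatic, c(1, 2, 3, 4, 5, 6))
  n_double <- if (nrow(g$bonds)) sum(g$bonds[, 3] == 2L) else 0L
  n_triple <- if (nrow(g$bonds)) sum(g$bonds[, 3] >= 3L) else 0L
  set_ladder(n_double, c(1, 2, 4, 8))
  set_ladder(n_triple, c(1, 2))
  set_ladder(sum(g$degree >= 3L), c(1, 2, 4, 8))
  set_ladder(sum(g$degree >= 4L), c(1, 2))
  hetero <- sum(!(g$elements %in% c("C", "H")))
  set_ladder(hetero, c(1, 2, 4, 8, 16))
  set_ladder(sum(g$elements %in% c("N", "O")), c(1, 2, 4, 8, 16))
  set_ladder(sum(g$elements %in% c("F", "Cl", "Br", "I")), c(1, 2, 4))
  bits
}

graph_components <- function(g) {
  if (g$n == 0L) return(0L)
  seen <- logical(g$n)
  ncomp <- 0L
  for (s in seq_len(g$n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      for (nb in g$adj[[v]]) {
        if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
      }
    }
  }
  ncomp
}

# -- SMARTS structural keys --------------------------------------------------

# Curated functional-group / ring key set (Klekota-Roth-style biologically
# oriented substructure keys, reduced to a compact panel).
SMARTS_KEYS <- c(
  "[CX4H3]", "C=C", "C#C", "c1ccccc1", "a1aaaa1", "[R]", "[R2]",
  "[nH]", "n", "o", "s", "[OX2H]", "c[OX2H]", "[#6][OX2][#6]",
  "C(=O)[OX2H1]", "C(=O)O[#6]", "C(=O)[NX3]", "[#6]C(=O)[#6]", "[CX3H1]=O",
  "[NX3;H2]", "[NX3;H1]([#6])[#6]", "[NX3]([#6])([#6])[#6]", "c[NX3]",
  "C=N", "C#N", "NC(=N)N", "NC(=O)N", "OC(=O)N",
  "[N+](=O)[O-]", "[SX2H]", "[#6][SX2][#6]", "S(=O)(=O)", "S(=O)(=O)N",
  "[F]", "[Cl]", "[Br]", "[I]", "C(F)(F)F",
  "[CX4]([#6])([#6])([#6])[#6]", "CC(C)C", "CCCC", "cC", "cO", "cCl",
  "[OR]", "[NR]", "[SR]", "c1ccncc1"
)
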