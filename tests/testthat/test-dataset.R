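# Row-by-row predicate oracle for the curation battery, independent of the
# sequential implementation in filter_activity_records().
curation_oracle <- function(targets, ligands, records,
                            terms = default_inactivity_terms()) {
  ok_t <- targets$target_id[targets$target_type %in%
                              c("Single protein", "Protein complex")]
  ok_l <- ligands$ligand_id[ligands$molecule_type == "Small_molecule" &
                              (is.na(ligands$prodrug_flag) |
                                 ligands$prodrug_flag != 1)]
  keep <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    com <- tolower(ifelse(is.na(r$activity_comment), "", r$activity_comment))
    r$target_id %in% ok_t && r$ligand_id %in% ok_l &&
      isTRUE(r$confidence_score > 5) && identical(r$standard_relation, "=") &&
      r$standard_type %in% c("IC50", "EC50", "Ki", "Kd") &&
      identical(r$standard_units, "nM") && isTRUE(r$standard_value > 0) &&
      !any(vapply(terms, function(t) grepl(t, com, fixed = TRUE), logical(1)))
  }, logical(1))
  records[keep, , drop = FALSE]
}

engineered_raw <- function() {
  targets <- tibble::tibble(
    target_id = c("T1", "T2", "T3"),
    name = c("Kinase A", "Receptor B", "Whole cell C"),
    target_type = c("Single protein", "Protein complex", "Organism"),
    organism = "Homo sapiens")
  ligands <- tibble::tibble(
    ligand_id = paste0("L", 1:5),
    canonical_smiles = c("c1ccccc1", "CCO", "CCN", "CCCC", "CCOC"),
    molecule_type = c(rep("Small_molecule", 4), "Protein"),
    prodrug_flag = c(0L, 0L, 1L, NA, 0L))
  # 20 records engineered so exactly 7 survive
  records <- dplyr::bind_rows(
    activity_row("L1", "T1", "IC50", 12),            # 1 ok
    activity_row("L1", "T1", "IC50", 340),           # 2 ok (duplicate pair)
    activity_row("L1", "T2", "Ki", 65),              # 3 ok
    activity_row("L2", "T1", "EC50", 1000),          # 4 ok
    activity_row("L2", "T2", "Kd", 5),               # 5 ok
    activity_row("L4", "T1", "Ki", 77),              # 6 ok (prodrug NA kept)
    activity_row("L4", "T2", "IC50", 0.4),           # 7 ok
    activity_row("L1", "T3", "IC50", 10),            # bad target_type
    activity_row("L5", "T1", "IC50", 10),            # bad molecule_type
    activity_row("L3", "T1", "IC50", 10),            # prodrug
    activity_row("L3", "T2", "Ki", 10),              # prodrug (second)
    activity_row("L1", "T1", "IC50", 10, confidence = 5L),   # confidence not >5
    activity_row("L1", "T1", "IC50", 10, confidence = 3L),   # confidence
    activity_row("L2", "T1", "IC50", 10, relation = ">"),    # relation
    activity_row("L2", "T1", "IC50", 10, relation = ">="),   # relation
    activity_row("L1", "T2", "AC50", 10),                    # type
    activity_row("L1", "T2", "IC50", 10, units = "uM"),      # units
    activity_row("L1", "T2", "IC50", 10, units = "ug.mL-1"), # units
    activity_row("L2", "T2", "IC50", -3),                    # nonpositive value
    activity_row("L2", "T2", "IC50", 10, comment = "Inactive at 10uM")) # comment
  list(targets = targets, ligands = ligands, records = records)
}

test_that("curation matches the row-by-row predicate oracle with per-rule counts", {
  raw <- engineered_raw()
  cur <- filter_activity_records(raw$targets, raw$ligands, raw$records)
  oracle <- curation_oracle(raw$targets, raw$ligands, raw$records)

  expect_equal(nrow(cur$activities), 7L)
  expect_identical(cur$activities, tibble::as_tibble(oracle))

  counts <- stats::setNames(cur$rejections$n_rejected, cur$rejections$rule)
  expect_identical(counts, c(target_type = 1L, molecule_type = 1L, prodrug = 2L,
                             confidence = 2L, relation = 2L, type = 1L,
                             units = 2L, value = 1L, comment = 1L))
  # entity tables restricted to rule-passing entities
  expect_identical(cur$targets$target_id, c("T1", "T2"))
  expect_identical(cur$ligands$ligand_id, c("L1", "L2", "L4"))
})

test_that("a confidence score of exactly 5 is rejected", {
  raw <- engineered_raw()
  one <- activity_row("L1", "T1", confidence = 5L)
  cur <- filter_activity_records(raw$targets, raw$ligands, one)
  expect_equal(nrow(cur$activities), 0L)
  expect_equal(cur$rejections$n_rejected[cur$rejections$rule == "confidence"], 1L)
})

test_that("empty inputs curate to empty outputs with zero counts", {
  raw <- engineered_raw()
  cur <- filter_activity_records(raw$targets[0, ], raw$ligands[0, ],
                                 raw$records[0, ])
  expect_equal(nrow(cur$activities), 0L)
  expect_true(all(cur$rejections$n_rejected == 0L))
})

test_that("curation is idempotent and survivor set is order-independent", {
  raw <- engineered_raw()
  cur1 <- filter_activity_records(raw$targets, raw$ligands, raw$records)
  cur2 <- filter_activity_records(cur1$targets, cur1$ligands, cur1$activities)
  expect_identical(cur2$activities, cur1$activities)
  expect_true(all(cur2$rejections$n_rejected == 0L))

  set.seed(3)
  perm <- sample.int(nrow(raw$records))
  shuffled <- filter_activity_records(raw$targets, raw$ligands,
                                      raw$records[perm, ])
  expect_identical(dplyr::arrange(shuffled$activities, ligand_id, target_id,
                                  standard_type, standard_value),
                   dplyr::arrange(cur1$activities, ligand_id, target_id,
                                  standard_type, standard_value))
})

test_that("missing mandatory columns raise schema errors naming the column", {
  raw <- engineered_raw()
  expect_error(filter_activity_records(raw$targets[, -3], raw$ligands,
                                       raw$records),
               "schema error.*target_type")
  expect_error(filter_activity_records(raw$targets, raw$ligands,
                                       raw$records[, setdiff(names(raw$records),
                                                             "standard_units")]),
               "schema error.*standard_units")
})

test_that("library build yields one panel per ligand and drops the unparseable", {
  targets <- tibble::tibble(
    target_id = paste0("T", 1:3), name = paste("Protein", 1:3),
    target_type = "Single protein", organism = "Homo sapiens")
  scaf <- c("c1ccccc1", "c1ccncc1", "C1CCNCC1")
  ligands <- purrr::map_dfr(1:3, function(t) tibble::tibble(
    ligand_id = sprintf("T%d_L%d", t, 1:5),
    canonical_smiles = paste0(c("C", "CC", "CCC", "OC", "NC"), scaf[t]),
    molecule_type = "Small_molecule", prodrug_flag = 0L))
  acts <- purrr::map_dfr(1:3, function(t) {
    activity_row(sprintf("T%d_L%d", t, 1:5), paste0("T", t),
                 value = c(10, 20, 30, 40, 50))
  })
  lib <- build_reference_library(list(targets = targets, ligands = ligands,
                                      activities = acts), timestamp = "t0")
  expect_equal(nrow(lib$targets), 3L)
  expect_equal(length(lib$panels$ids), 15L)
  expect_identical(lib$panels$ids, lib$ligands$ligand_id)

  # one bad structure among ten: dropped with its activities, logged
  ligands2 <- ligands[1:10, ]
  ligands2$canonical_smiles[4] <- "C1CC("
  lib2 <- build_reference_library(list(targets = targets[1:2, ],
                                       ligands = ligands2,
                                       activities = acts[1:10, ]),
                                  timestamp = "t0")
  expect_equal(length(lib2$panels$ids), 9L)
  expect_identical(lib2$metadata$dropped_ligands$ligand_id, "T1_L4")
  expect_false("T1_L4" %in% lib2$activities$ligand_id)

  # determinism: rebuilding from the same inputs reproduces the library
  lib3 <- build_reference_library(list(targets = targets, ligands = ligands,
                                       activities = acts), timestamp = "t0")
  expect_identical(lib3$panels$bits, lib$panels$bits)
  expect_identical(lib3$activities, lib$activities)
})

test_that("best_activity returns the most potent record or NA", {
  lib <- make_manual_library(
    panels = list(A = 1:8, B = 2:9),
    activities = dplyr::bind_rows(
      activity_row("A", "T1", "IC50", 340),
      activity_row("A", "T1", "IC50", 12),
      activity_row("B", "T1", "Ki", 65)))
  expect_equal(best_activity(lib, "A", "T1", "IC50"), 12)
  expect_equal(best_activity(lib, "B", "T1", "Ki"), 65)
  expect_true(is.na(best_activity(lib, "A", "T1", "Kd")))
  expect_error(best_activity(lib, "Z", "T1", "IC50"), "unknown ligand_id")
  expect_error(best_activity(lib, "A", "T9", "IC50"), "unknown target_id")
})

test_that("library bundles round-trip bit-identically", {
  lib <- standard_library()
  dir <- withr::local_tempdir()
  bundle <- file.path(dir, "bundle")
  save_library(lib, bundle)
  back <- load_library(bundle)

  expect_identical(back$targets, lib$targets)
  expect_identical(back$ligands, lib$ligands)
  expect_identical(back$activities, lib$activities)
  expect_identical(back$panels$bits, lib$panels$bits)
  expect_identical(back$panels$n_on, lib$panels$n_on)
  expect_identical(back$metadata$source_name, lib$metadata$source_name)
  expect_identical(back$metadata$built, lib$metadata$built)
  expect_identical(back$metadata$dropped_ligands, lib$metadata$dropped_ligands)

  # panels computed under the restored config match the originals
  q1 <- compute_panels(lib$ligands$canonical_smiles[1], back$config)
  q2 <- compute_panels(lib$ligands$canonical_smiles[1], lib$config)
  expect_identical(q1$bits, q2$bits)
})

test_that("incompatible bundles fail loudly, not silently", {
  lib <- standard_library()
  dir <- withr::local_tempdir()
  bundle <- file.path(dir, "bundle")
  save_library(lib, bundle)

  expect_error(load_library(file.path(dir, "nope")), "manifest")

  # truncated fingerprint block
  fp <- readLines(file.path(bundle, "fingerprints.tsv"))
  writeLines(fp[1:10], file.path(bundle, "fingerprints.tsv"))
  expect_error(load_library(bundle), "incompatible|incomplete")

  # wrong layout version
  save_library(lib, bundle, overwrite = TRUE)
  mf <- jsonlite::read_json(file.path(bundle, "manifest.json"))
  mf$layout_version <- "999"
  jsonlite::write_json(mf, file.path(bundle, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(load_library(bundle), "layout version")
})
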