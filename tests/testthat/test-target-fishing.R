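# Exhaustive max+count oracle over an explicit similarity matrix.
score_oracle <- function(sim_matrix, thresholds) {
  best <- apply(sim_matrix, 1, max)
  sum(best >= thresholds)
}

test_that("consensus score equals the brute-force max+count oracle", {
  set.seed(11)
  kinds <- fingerprint_kinds()
  for (rep in 1:20) {
    # 3-ligand toy target with random 64-bit vectors per kind
    lig_panels <- lapply(1:3, function(i) {
      p <- lapply(kinds, function(k) sample.int(64, sample(4:20, 1)))
      names(p) <- kinds
      p
    })
    names(lig_panels) <- paste0("L", 1:3)
    q_bits <- lapply(kinds, function(k) sample.int(64, sample(4:20, 1)))
    names(q_bits) <- kinds

    ref <- make_manual_fpset(lig_panels)
    qp <- make_manual_fpset(list(Q = q_bits))
    params <- fishing_params(thresholds = 0.5)

    st <- score_target(qp, ref, params)
    sims <- vapply(paste0("L", 1:3), function(l) {
      vapply(kinds, function(k) tanimoto_oracle(q_bits[[k]],
                                                lig_panels[[l]][[k]]),
             numeric(1))
    }, numeric(13))
    expect_equal(st$score, score_oracle(sims, rep(0.5, 13)))
    expect_equal(unname(st$per_kind_best), unname(apply(sims, 1, max)))
  }
})

test_that("identity attains score 13 and total dissimilarity scores 0", {
  lib <- standard_library()
  params <- fishing_params()
  q <- library_ligand_panel(lib, lib$panels$ids[1])
  own_target <- lib$activities$target_id[
    lib$activities$ligand_id == lib$panels$ids[1]][1]
  st <- score_target(q, ligfish:::target_panel_set(lib, own_target), params)
  expect_equal(st$score, 13L)
  expect_equal(unname(st$per_kind_best), rep(1, 13))

  # orthogonal bit patterns: all similarities 0
  ref <- make_manual_fpset(list(A = 1:8, B = 9:16))
  qp <- make_manual_fpset(list(Q = 17:24))
  st0 <- score_target(qp, ref, fishing_params())
  expect_equal(st0$score, 0L)

  expect_error(score_target(qp, ligfish:::fp_set_subset(ref, integer(0)),
                            params),
               "no reference ligand")
})

test_that("reliability is a cutoff sweep on the score", {
  for (s in c(0L, 5L, 13L)) {
    for (cutoff in 0:13) {
      params <- fishing_params(reliability_min_score = cutoff)
      expect_identical(assess_reliability(s, params), s >= cutoff)
    }
  }
  expect_error(assess_reliability(14L, fishing_params()), "score")
})

test_that("raising any threshold never increases a score", {
  set.seed(23)
  kinds <- fingerprint_kinds()
  lig_panels <- lapply(1:4, function(i) {
    p <- lapply(kinds, function(k) sample.int(64, 12))
    names(p) <- kinds
    p
  })
  names(lig_panels) <- paste0("L", 1:4)
  ref <- make_manual_fpset(lig_panels)
  qp <- make_manual_fpset(list(Q = stats::setNames(
    lapply(kinds, function(k) sample.int(64, 12)), kinds)))

  base_thr <- stats::setNames(rep(0.3, 13), kinds)
  base <- score_target(qp, ref, fishing_params(thresholds = base_thr))$score
  for (k in kinds) {
    for (delta in c(0.2, 0.5)) {
      thr <- base_thr
      thr[k] <- thr[k] + delta
      s <- score_target(qp, ref, fishing_params(thresholds = thr))$score
      expect_lte(s, base)
    }
  }
})

test_that("adding a ligand to a target never decreases its score", {
  set.seed(31)
  kinds <- fingerprint_kinds()
  mk <- function() stats::setNames(lapply(kinds, function(k)
    sample.int(64, 10)), kinds)
  panels <- stats::setNames(lapply(1:5, function(i) mk()), paste0("L", 1:5))
  qp <- make_manual_fpset(list(Q = mk()))
  params <- fishing_params(thresholds = 0.2)
  for (n in 1:4) {
    s_n <- score_target(qp, make_manual_fpset(panels[1:n]), params)$score
    s_n1 <- score_target(qp, make_manual_fpset(panels[1:(n + 1)]), params)$score
    expect_gte(s_n1, s_n)
  }
})

test_that("fishing ranks by score with deterministic tie-breaks", {
  lib <- standard_library()
  q <- library_ligand_panel(lib, lib$panels$ids[1])
  r1 <- fish_targets(q, lib)
  r2 <- fish_targets(q, lib)
  expect_identical(tibble::as_tibble(r1), tibble::as_tibble(r2))
  expect_true(all(diff(r1$score) <= 0))
  # within equal scores, mean_best is non-increasing
  for (s in unique(r1$score)) {
    mb <- r1$mean_best[r1$score == s]
    expect_true(all(diff(mb) <= 1e-12))
  }
  expect_identical(r1$rank, seq_len(nrow(r1)))
})

test_that("the report size honours the minimum and the reliable-always rule", {
  lib <- standard_library()  # 8 targets: capped at library size
  q <- library_ligand_panel(lib, lib$panels$ids[1])
  r <- fish_targets(q, lib, fishing_params(min_reported_targets = 30))
  expect_equal(nrow(r), nrow(lib$targets))

  r3 <- fish_targets(q, lib, fishing_params(min_reported_targets = 3))
  expect_gte(nrow(r3), 3L)
  expect_true(all(r3$reliable[r3$score >= 7]))

  # when reliable targets exceed the minimum, all of them are shown
  r_all <- fish_targets(q, lib, fishing_params(min_reported_targets = 1,
                                               reliability_min_score = 0))
  expect_equal(nrow(r_all), nrow(lib$targets))
})

test_that("similarity analysis ranks the identical ligand first, fully flagged", {
  lib <- standard_library()
  lid <- lib$panels$ids[1]
  tid <- lib$activities$target_id[lib$activities$ligand_id == lid][1]
  q <- library_ligand_panel(lib, lid)
  ev <- similarity_analysis(q, tid, lib, top_n = 50)
  expect_identical(ev$ligand_id[1], lid)
  expect_true(all(ev$over_threshold[[1]]))
  expect_equal(ev$mean_similarity[1], 1)
  # top_n larger than the ligand count returns all ligands
  n_lig <- length(unique(lib$activities$ligand_id[
    lib$activities$target_id == tid]))
  expect_equal(nrow(ev), n_lig)
  # ranking equals an independent sort of mean similarities
  expect_identical(ev$mean_similarity, sort(ev$mean_similarity,
                                            decreasing = TRUE))
  expect_error(similarity_analysis(q, "T999", lib), "unknown target_id")
})

test_that("every fixture ligand fishes its own target at rank 1 with score 13", {
  lib <- standard_library()
  own <- lib$activities$target_id[match(lib$panels$ids,
                                        lib$activities$ligand_id)]
  for (i in seq_along(lib$panels$ids)) {
    q <- ligfish:::fp_set_subset(lib$panels, i)
    r <- fish_targets(q, lib)
    hit <- r[r$target_id == own[i], ]
    expect_equal(hit$score, 13L)
    # rank 1 up to ties on (score, mean_best)
    better <- r[r$score > hit$score |
                  (r$score == hit$score & r$mean_best > hit$mean_best), ]
    expect_equal(nrow(better), 0L)
  }
})
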