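test_that("pActivity transform is definitional and invertible", {
  expect_equal(to_p_activity(1), 9)
  expect_equal(to_p_activity(1000), 6)
  for (x in c(0.1, 65.6, 860)) {
    expect_equal(from_p_activity(to_p_activity(x)), x, tolerance = 1e-9)
  }
  expect_error(to_p_activity(0), "positive")
  expect_error(to_p_activity(-5), "positive")
})

test_that("singleton identity predicts the neighbour's value with zero variance", {
  lib <- make_manual_library(
    panels = list(A = c(1, 5, 9, 12)),
    activities = activity_row("A", "T1", "IC50", 65))
  qp <- make_manual_fpset(list(Q = c(1, 5, 9, 12)))
  pred <- predict_activity(qp, "T1", "IC50", lib)
  expect_equal(pred$value_nM, 65, tolerance = 1e-12)
  expect_equal(pred$variance, 0)
  expect_equal(pred$neighbors$tau, 1)
})

test_that("two equal-weight neighbours give the closed-form mean and variance", {
  # both neighbours identical to the query: weights equal; pActivities 6
  # (1000 nM) and 8 (10 nM) -> prediction pActivity 7 = 100 nM, variance 1
  lib <- make_manual_library(
    panels = list(A = 1:10, B = 1:10),
    activities = dplyr::bind_rows(
      activity_row("A", "T1", "IC50", 1000),
      activity_row("B", "T1", "IC50", 10)))
  qp <- make_manual_fpset(list(Q = 1:10))
  pred <- predict_activity(qp, "T1", "IC50", lib)
  expect_equal(pred$p_activity, 7)
  expect_equal(pred$value_nM, 100, tolerance = 1e-12)
  expect_equal(pred$variance, 1)
  expect_equal(pred$neighbors$tau, c(0.5, 0.5))
})

test_that("no qualifying neighbour means no prediction", {
  lib <- make_manual_library(
    panels = list(A = 1:10),
    activities = activity_row("A", "T1", "IC50", 100))
  # query orthogonal to A: mean similarity 0 < 0.5
  qp <- make_manual_fpset(list(Q = 21:30))
  expect_null(predict_activity(qp, "T1", "IC50", lib))
  # type absent entirely
  qp2 <- make_manual_fpset(list(Q = 1:10))
  expect_null(predict_activity(qp2, "T1", "Kd", lib))
  expect_error(predict_activity(qp2, "T9", "IC50", lib), "unknown target_id")
  expect_error(predict_activity(qp2, "T1", "XC50", lib), "arg")
})

test_that("neighbours use the best (minimum nM) record per ligand and type", {
  lib <- make_manual_library(
    panels = list(A = 1:10),
    activities = dplyr::bind_rows(
      activity_row("A", "T1", "IC50", 340),
      activity_row("A", "T1", "IC50", 12)))
  qp <- make_manual_fpset(list(Q = 1:10))
  pred <- predict_activity(qp, "T1", "IC50", lib)
  expect_equal(pred$value_nM, 12, tolerance = 1e-12)
})

test_that("the prediction stays within the neighbours' observed range", {
  set.seed(5)
  for (rep in 1:10) {
    vals <- 10^stats::runif(4, 0, 4)
    panels <- list(A = 1:10, B = c(1:7, 11:13), C = c(1:6, 14:17),
                   D = c(1:8, 18:19))
    lib <- make_manual_library(
      panels = panels,
      activities = purrr::map_dfr(seq_along(panels), function(i) {
        activity_row(names(panels)[i], "T1", "Ki", vals[i])
      }))
    qp <- make_manual_fpset(list(Q = 1:10))
    pred <- predict_activity(qp, "T1", "Ki", lib)
    expect_gte(pred$value_nM, min(vals) * (1 - 1e-12))
    expect_lte(pred$value_nM, max(vals) * (1 + 1e-12))
  }
})

test_that("scaling every activity by 10 shifts the prediction, not the variance", {
  panels <- list(A = 1:10, B = c(1:8, 11:12), C = c(1:7, 13:15))
  vals <- c(20, 300, 80)
  mk <- function(scale) make_manual_library(
    panels = panels,
    activities = purrr::map_dfr(1:3, function(i) {
      activity_row(names(panels)[i], "T1", "EC50", vals[i] * scale)
    }))
  qp <- make_manual_fpset(list(Q = 1:10))
  p1 <- predict_activity(qp, "T1", "EC50", mk(1))
  p10 <- predict_activity(qp, "T1", "EC50", mk(10))
  expect_equal(p10$value_nM / p1$value_nM, 10, tolerance = 1e-9)
  expect_equal(p10$variance, p1$variance, tolerance = 1e-12)
})

test_that("growing weight_power drives the prediction toward the nearest neighbour", {
  panels <- list(near = 1:10, far = c(1:5, 11:15))
  lib <- make_manual_library(
    panels = panels,
    activities = dplyr::bind_rows(
      activity_row("near", "T1", "IC50", 10),    # pActivity 8
      activity_row("far", "T1", "IC50", 1000)))  # pActivity 6
  qp <- make_manual_fpset(list(Q = 1:10))
  params <- lapply(c(1, 3, 8, 20), function(w)
    bioactivity_params(neighbor_min_similarity = 0.1, weight_power = w))
  preds <- vapply(params, function(p)
    predict_activity(qp, "T1", "IC50", lib, p)$p_activity, numeric(1))
  expect_true(all(diff(preds) > 0))
  expect_lt(abs(preds[4] - 8), 0.05)
})

test_that("profiling ranks targets by ascending sigma_p with identity tied first", {
  lib <- standard_library()
  lid <- lib$panels$ids[1]
  own <- lib$activities$target_id[lib$activities$ligand_id == lid][1]
  q <- library_ligand_panel(lib, lid)
  prof <- profile_bioactivity(q, lib)
  expect_true(all(diff(prof$sigma_p) >= -1e-12))
  top_tied <- prof$target_id[prof$sigma_p <= prof$sigma_p[1] + 1e-12]
  expect_true(own %in% top_tied)
  # per-row invariants
  for (i in seq_len(nrow(prof))) {
    vals <- unlist(prof[i, c("IC50", "EC50", "Ki", "Kd")])
    expect_true(any(!is.na(vals)))
    expect_true(prof$best_type[i] %in% names(vals)[!is.na(vals)])
  }
})

test_that("profile ordering equals a brute-force sort of recomputed variances", {
  lib <- standard_library()
  q <- library_ligand_panel(lib, lib$panels$ids[7])
  prof <- profile_bioactivity(q, lib)
  params <- bioactivity_params()
  recomputed <- vapply(prof$target_id, function(tid) {
    vars <- vapply(c("IC50", "EC50", "Ki", "Kd"), function(ty) {
      p <- predict_activity(q, tid, ty, lib, params)
      if (is.null(p)) NA_real_ else p$variance
    }, numeric(1))
    min(vars, na.rm = TRUE)
  }, numeric(1))
  expect_equal(unname(recomputed), prof$sigma_p, tolerance = 1e-12)
  expect_identical(prof$sigma_p, sort(prof$sigma_p))
})

test_that("a library where one target has qualifying neighbours yields one row", {
  lib <- make_manual_library(
    panels = list(A = 1:10, B = 31:40),
    activities = dplyr::bind_rows(
      activity_row("A", "T1", "IC50", 50),
      activity_row("B", "T2", "Ki", 200)))
  qp <- make_manual_fpset(list(Q = 1:10))
  prof <- profile_bioactivity(qp, lib)
  expect_equal(nrow(prof), 1L)
  expect_equal(prof$target_id, "T1")
})
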