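toy_data <- function(values_by_pert, stim_value = 1L, node = "r",
                     times = c(0, 10)) {
  rows <- list()
  perts <- names(values_by_pert)
  for (p in perts) {
    rows[[p]] <- tibble::tibble(
      perturbation = p, time = times[seq_along(values_by_pert[[p]])],
      node = node, value = values_by_pert[[p]]
    )
  }
  pert_ts(
    dplyr::bind_rows(rows),
    tibble::tibble(perturbation = perts, node = "s", value = stim_value)
  )
}

test_that("rmse evaluates the objective exactly", {
  d <- toy_data(list(p01 = c(0.2, 0.8)))
  pred <- d
  pred$measurements$value <- c(0, 1)
  pred$binarized <- TRUE
  expect_equal(rmse(d, pred), sqrt((0.04 + 0.04) / 2))
  # exact binary data fits with zero error
  db <- toy_data(list(p01 = c(0, 1)))
  expect_equal(rmse(db, pred), 0)
  # all-ones data against all-zero prediction is maximal
  d1 <- toy_data(list(p01 = c(1, 1)))
  pred0 <- d1
  pred0$measurements$value <- c(0, 0)
  expect_equal(rmse(d1, pred0), 1)
  # shape mismatch
  bad <- pred
  bad$measurements <- bad$measurements[1, ]
  expect_error(rmse(d, bad), "do not match")
})

test_that("discrete_rmse is the binarization floor with ties to 1", {
  expect_equal(discrete_rmse(toy_data(list(p01 = c(0, 1)))), 0)
  expect_equal(discrete_rmse(toy_data(list(p01 = c(0.2, 0.8)))), 0.2)
  d <- toy_data(list(p01 = c(0.5, 1)))
  # 0.5 binarizes to 1, contributing 0.5^2
  expect_equal(discrete_rmse(d), sqrt(0.25 / 2))
})

test_that("learn recovers the stimulated-readout toy model exactly", {
  net <- pkn(tibble::tibble(source = "s", sign = 1L, target = "r"),
    roles = c(s = "stimulus", r = "readout")
  )
  d <- toy_data(list(p01 = c(0.1, 0.9)))
  fit <- learn(net, d)
  expect_s3_class(fit, "bn_learn")
  expect_true(fit$proven_optimal)
  best <- fit$results[[1]]
  expect_equal(bn_hyperedges(best$bn)$hyperedge, "r <- s")
  expect_equal(unname(best$traces$p01[, "r"]), c(0L, 1L))
  expect_equal(best$model_rmse, sqrt((0.01 + 0.01) / 2))
  expect_equal(best$model_rmse, best$discrete_rmse)
  expect_equal(nrow(best$penalized_points), 0L)
})

test_that("max_models caps the returned optima and flags truncation", {
  # both-signs parallel edges give co-optimal candidates
  net <- pkn(
    tibble::tibble(
      source = c("s", "s2"), sign = c(1L, 1L), target = c("r", "r")
    ),
    roles = c(s = "stimulus", s2 = "stimulus", r = "readout")
  )
  d <- pert_ts(
    tibble::tibble(
      perturbation = "p01", time = c(0, 10), node = "r", value = c(0.1, 0.9)
    ),
    tibble::tibble(perturbation = "p01", node = c("s", "s2"), value = 1L)
  )
  fit_all <- learn(net, d, learn_config(max_models = 50))
  expect_gt(length(fit_all$results), 1L)
  fit1 <- learn(net, d, learn_config(max_models = 1))
  expect_length(fit1$results, 1L)
  expect_true(fit1$truncated)
})

test_that("the learner matches brute force on small random instances", {
  # broader seeded sweep lives in the acceptance suite; spot-check here
  for (seed in c(2, 5)) {
    inst <- random_instance(seed, n_nodes = 3L, n_perts = 2L, k = 3L)
    fit <- learn(inst$net, inst$data, learn_config(
      max_clauses_per_node = 2L, order = "canonical", max_models = 5
    ))
    oracle <- brute_force_learn(inst$net, inst$data,
      max_clauses_per_node = 2L
    )
    expect_equal(fit$objective, oracle, tolerance = 1e-9, info = paste("seed", seed))
  }
})

test_that("all returned optima share one objective and satisfy the floor bound", {
  inst <- random_instance(11, n_nodes = 4L, n_perts = 2L, k = 3L)
  fit <- learn(inst$net, inst$data, learn_config(max_models = 30))
  objs <- purrr::map_dbl(fit$results, "model_rmse")
  expect_true(all(abs(objs - fit$objective) < 1e-9))
  for (r in fit$results) {
    expect_gte(r$model_rmse, r$discrete_rmse - 1e-12)
    expect_lte(rmse_ratio(r$discrete_rmse, r$model_rmse), 1 + 1e-12)
  }
})

test_that("restricting perturbations with a fixed normalizer never raises the optimum", {
  inst <- random_instance(23, n_nodes = 3L, n_perts = 2L, k = 3L)
  fit_full <- learn(inst$net, inst$data, learn_config(max_models = 1))
  sub <- inst$data
  keep <- pts_perturbations(sub)[1]
  sub$measurements <- sub$measurements[sub$measurements$perturbation == keep, ]
  sub$perturbations <- sub$perturbations[sub$perturbations$perturbation == keep, ]
  fit_sub <- learn(inst$net, sub, learn_config(max_models = 1))
  # compare raw sums of squares: optimum over fewer perturbations, with the
  # full normalizer held fixed, cannot exceed the full-data optimum
  k <- length(pts_timepoints(inst$data))
  m <- length(pts_observed(inst$data))
  full_cells <- m * k * 2
  ss_full <- fit_full$objective^2 * full_cells
  ss_sub <- fit_sub$objective^2 * (m * k * 1)
  expect_lte(ss_sub, ss_full + 1e-9)
})

test_that("trace states respect clamping and consecutive support consistency", {
  inst <- random_instance(31, n_nodes = 4L, n_perts = 2L, k = 3L)
  fit <- learn(inst$net, inst$data, learn_config(max_models = 3))
  for (r in fit$results) {
    for (p in names(r$traces)) {
      cl <- clamping(pts_settings(inst$data, p), inst$net$roles)
      tr <- r$traces[[p]]
      for (j in seq_len(nrow(tr))) {
        if (length(cl) > 0L) expect_equal(unname(tr[j, names(cl)]), unname(cl))
        if (j > 1L) {
          expect_true(support_consistent(r$bn, tr[j - 1L, ], tr[j, ], cl))
        }
      }
    }
  }
})

test_that("adopting the corrected points lets the same network fit exactly", {
  # a noisy instance that forces penalized points, then refit on corrected data
  inst <- random_instance(47, n_nodes = 3L, n_perts = 2L, k = 3L)
  fit <- learn(inst$net, inst$data, learn_config(max_models = 1))
  best <- fit$results[[1]]
  corrected <- best$corrected
  corrected$binarized <- FALSE # 0/1 values are valid normalized measurements
  fam <- bn_family(list(best$bn))
  refit <- family_best_fit(fam, corrected, inst$net$roles)
  expect_equal(refit$model_rmse, 0)
  expect_equal(refit$discrete_rmse, 0)
})
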