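make_ts <- function(values, perts = "p01", nodes = "r", times = NULL,
                    settings = NULL) {
  # values: array-like list per perturbation of k x m matrices (or vectors)
  rows <- list()
  for (p in perts) {
    v <- values[[p]]
    if (is.null(dim(v))) v <- matrix(v, ncol = length(nodes))
    if (is.null(times)) times <- seq_len(nrow(v)) * 10 - 10
    rows[[p]] <- tibble::tibble(
      perturbation = p,
      time = rep(times, each = length(nodes)),
      node = rep(nodes, nrow(v)),
      value = as.vector(t(v))
    )
  }
  if (is.null(settings)) {
    settings <- tibble::tibble(perturbation = perts, node = "s", value = 1L)
  }
  pert_ts(dplyr::bind_rows(rows), settings)
}

test_that("normalize divides by each node's global maximum", {
  x <- make_ts(list(p01 = c(0.2, 0.4)))
  nx <- normalize(x)
  expect_equal(nx$measurements$value, c(0.5, 1.0))
  # constant node maps to all ones
  cx <- normalize(make_ts(list(p01 = c(0.7, 0.7, 0.7))))
  expect_equal(cx$measurements$value, rep(1, 3))
  # all-zero node is an error naming the node
  expect_error(normalize(make_ts(list(p01 = c(0, 0)))), "r")
})

test_that("normalization is idempotent and sets each node's max to 1", {
  set.seed(11)
  vals <- matrix(runif(12, 0.1, 5), nrow = 4)
  x <- make_ts(
    list(p01 = vals[1:2, ], p02 = vals[3:4, ]),
    perts = c("p01", "p02"), nodes = c("a", "b", "c")
  )
  n1 <- normalize(x)
  n2 <- normalize(n1)
  expect_equal(n1$measurements$value, n2$measurements$value)
  mx <- tapply(n1$measurements$value, n1$measurements$node, max)
  expect_equal(as.numeric(mx), rep(1, 3))
})

test_that("binarize thresholds with ties mapping to 1", {
  x <- make_ts(list(p01 = c(0.2, 0.8, 0.5, 0.49)))
  b <- binarize(normalize(make_ts(list(p01 = c(0.2, 0.8, 0.5, 0.49) * 1)))) # max=0.8
  expect_true(b$binarized)
  x2 <- make_ts(list(p01 = c(0.2, 0.8)))
  expect_equal(binarize(x2, 0.5)$measurements$value, c(0, 1))
  expect_equal(binarize(make_ts(list(p01 = 0.5)), 0.5)$measurements$value, 1)
  expect_equal(binarize(make_ts(list(p01 = rep(0.49, 3))), 0.5)$measurements$value, rep(0, 3))
  xm <- make_ts(list(p01 = c(0.2, NA)))
  expect_error(binarize(xm), "missing")
})

test_that("binarize-after-normalize is invariant to positive per-node rescaling", {
  set.seed(3)
  vals <- matrix(runif(20, 0, 2), nrow = 5)
  x <- make_ts(list(p01 = vals), nodes = paste0("n", 1:4))
  scaled <- x
  fac <- c(n1 = 3, n2 = 0.25, n3 = 10, n4 = 1)
  scaled$measurements$value <- scaled$measurements$value *
    fac[scaled$measurements$node]
  b1 <- binarize(normalize(x))
  b2 <- binarize(normalize(scaled))
  expect_equal(b1$measurements$value, b2$measurements$value)
})

test_that("qc_repair applies steps 2-5 and reports every action", {
  roles <- c(s = "stimulus", akt = "inhibitor_and_readout", r = "readout")
  times <- c(0, 10, 20)
  meas <- tibble::tibble(
    perturbation = rep(c("p01", "p02", "p03"), each = 6),
    time = rep(rep(times, each = 2), 3),
    node = rep(c("akt", "r"), 9),
    value = c(
      # p01: missing t0 for r, fillable from control
      0.1, NA, 0.1, 0.6, 0.1, 0.7,
      # p02: akt inhibited but oscillating -> step-4 drop
      0.9, 0.5, 0.1, 0.5, 0.9, 0.5,
      # p03: clean
      0.1, 0.4, 0.1, 0.5, 0.1, 0.6
    )
  )
  # add a duplicated reading in p03 at t=10 for r (step-3 keeps first)
  meas <- dplyr::bind_rows(meas, tibble::tibble(
    perturbation = "p03", time = 10, node = "r", value = 0.99
  ))
  setts <- tibble::tibble(
    perturbation = rep(c("p01", "p02", "p03"), each = 2),
    node = rep(c("s", "akt"), 3),
    value = c(1L, 0L, 1L, 1L, 1L, 0L)
  )
  x <- pert_ts(meas, setts)
  res <- qc_repair(x, roles, control = c(r = 0.3), tolerance = 0.2)

  expect_setequal(unique(res$report$rule), c("step-2", "step-3", "step-4"))
  # step-2 filled the missing t0 with the control value
  filled <- res$data$measurements %>%
    dplyr::filter(perturbation == "p01", time == 0, node == "r")
  expect_equal(filled$value, 0.3)
  # step-3 kept the first duplicate
  kept <- res$data$measurements %>%
    dplyr::filter(perturbation == "p03", time == 10, node == "r")
  expect_equal(kept$value, 0.5)
  # step-4 dropped the oscillating inhibited perturbation (range 0.8 > 0.2)
  expect_false("p02" %in% pts_perturbations(res$data))
  s4 <- res$report[res$report$rule == "step-4", ]
  expect_equal(s4$perturbation, "p02")
  expect_equal(s4$node, "akt")
})

test_that("step-5 drops perturbations with unfillable missing points", {
  roles <- c(s = "stimulus")
  x <- make_ts(list(p01 = c(0.2, NA, 0.4), p02 = c(0.1, 0.2, 0.3)),
    perts = c("p01", "p02"),
    settings = tibble::tibble(perturbation = c("p01", "p02"), node = "s", value = 1L)
  )
  res <- qc_repair(x, roles)
  expect_equal(pts_perturbations(res$data), "p02")
  expect_equal(res$report$rule, "step-5")
})

test_that("a clean dataset is a qc fixpoint with an empty report", {
  roles <- c(s = "stimulus")
  x <- make_ts(list(p01 = c(0.2, 0.3, 0.4)))
  res <- qc_repair(x, roles)
  expect_equal(nrow(res$report), 0L)
  expect_equal(res$data$measurements, x$measurements)
})

test_that("replaying the qc report reconstructs the repaired dataset", {
  cfg <- sim_config(
    seed = 21, noise_sd = 0.05,
    defects = c("missing_t0", "duplicate_timepoint", "inhibitor_dynamic")
  )
  net <- generate_pkn(cfg)
  raw <- simulate_dataset(sample_true_bn(net, seed = 21), net, cfg)
  res <- qc_repair(raw, net$roles, control = attr(raw, "control"), tolerance = 0.4)
  replayed <- qc_replay(raw, res$report)
  expect_equal(
    dplyr::arrange(replayed$measurements, perturbation, time, node),
    dplyr::arrange(res$data$measurements, perturbation, time, node)
  )
  # surviving perturbations are a subset of the input's
  expect_true(all(pts_perturbations(res$data) %in% pts_perturbations(raw)))
})

test_that("MIDAS round-trip preserves the dataset", {
  cfg <- sim_config(seed = 9, noise_sd = 0.02)
  net <- generate_pkn(cfg)
  raw <- simulate_dataset(sample_true_bn(net, seed = 9), net, cfg)
  f <- withr::local_tempfile(fileext = ".csv")
  write_midas(raw, f, roles = net$roles)
  back <- read_midas(f)
  key <- function(m) dplyr::arrange(m, perturbation, time, node)
  expect_equal(key(back$measurements)$value, key(raw$measurements)$value,
    tolerance = 1e-6
  )
  expect_equal(
    sort(unique(back$perturbations$node)),
    sort(unique(raw$perturbations$node))
  )
  # roles inferred from the header match the generator's
  inferred <- attr(back, "roles")
  expect_equal(
    sort(names(inferred)[inferred == "stimulus"]),
    sort(pkn_nodes(net, "stimulus"))
  )
})
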