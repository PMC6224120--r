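mk_bn <- function(nodes, ...) boolean_network(nodes, list(...))

test_that("jaccard follows the intersection-over-union definition", {
  a <- c("x <- a", "y <- b", "z <- c")
  b <- c("x <- a", "y <- b", "w <- d")
  expect_equal(jaccard(a, b), 2 / 4)
  expect_equal(jaccard(a, a), 1)
  expect_equal(jaccard(a, c("q <- r")), 0)
  expect_equal(jaccard(character(0), character(0)), 1)
  # symmetry and bounds on random sets
  set.seed(8)
  for (i in 1:10) {
    s1 <- sample(letters, sample(0:10, 1))
    s2 <- sample(letters, sample(0:10, 1))
    expect_equal(jaccard(s1, s2), jaccard(s2, s1))
    expect_gte(jaccard(s1, s2), 0)
    expect_lte(jaccard(s1, s2), 1)
    if (length(s1) > 0 || length(s2) > 0) {
      expect_equal(jaccard(s1, s2) == 1, setequal(s1, s2))
    }
  }
})

test_that("hyperedge frequencies count family membership", {
  nodes <- c("a", "b", "c")
  b1 <- mk_bn(nodes, b = list(c(a = 1)), c = list(c(b = 1)))
  b2 <- mk_bn(nodes, b = list(c(a = 1)))
  b3 <- mk_bn(nodes, b = list(c(a = 1)), c = list(c(a = -1)))
  fam <- bn_family(list(b1, b2, b3), label = "fam")
  fr <- hyperedge_frequencies(fam)
  expect_equal(fr$frequency[fr$hyperedge == "b <- a"], 1)
  expect_equal(fr$frequency[fr$hyperedge == "c <- b"], 1 / 3)
  expect_false("c <- c" %in% fr$hyperedge)
})

test_that("aggregation keeps strictly-above-threshold hyper-edges", {
  nodes <- c("a", "b")
  members <- c(
    replicate(4, mk_bn(nodes, b = list(c(a = 1))), simplify = FALSE),
    replicate(6, mk_bn(nodes), simplify = FALSE)
  )
  fam <- bn_family(members)
  # frequency 0.4 > 0.3 kept
  expect_equal(aggregate_family(fam, 0.3)$hyperedges$hyperedge, "b <- a")
  # frequency exactly at the threshold dropped
  expect_equal(nrow(aggregate_family(fam, 0.4)$hyperedges), 0L)
  # threshold 0 reproduces the union; thresholds are monotone
  fam2 <- bn_family(list(
    mk_bn(nodes, b = list(c(a = 1))), mk_bn(nodes, b = list(c(a = -1)))
  ))
  expect_setequal(
    aggregate_family(fam2, 0)$hyperedges$hyperedge,
    c("b <- a", "b <- !a")
  )
  for (th in c(0, 0.2, 0.5, 0.8)) {
    lo <- aggregate_family(fam, th)$hyperedges$hyperedge
    hi <- aggregate_family(fam, min(th + 0.2, 0.99))$hyperedges$hyperedge
    expect_true(all(hi %in% lo))
  }
})

test_that("family similarity is the mean Jaccard to the gold standard", {
  nodes <- c("a", "b", "c")
  gold <- c("b <- a", "c <- b")
  # member 1 matches exactly (jaccard 1); member 2 shares one of three
  b1 <- mk_bn(nodes, b = list(c(a = 1)), c = list(c(b = 1)))
  b2 <- mk_bn(nodes, b = list(c(a = 1)), c = list(c(a = 1)))
  fam <- bn_family(list(b1, b2))
  expect_equal(family_similarity(gold, fam), (1 + 1 / 3) / 2)
  # identical family against its own network
  fam_id <- bn_family(list(b1, b1))
  expect_equal(family_similarity(b1, fam_id), 1)
  # similarity matrix carries both orientations
  sm <- similarity_matrix(list(
    bn_family(list(b1), label = "A"), bn_family(list(b2), label = "B")
  ), threshold = 0)
  expect_equal(nrow(sm), 4L)
  expect_equal(sm$similarity[sm$gold == "A" & sm$family == "A"], 1)
})

test_that("rmse_ratio handles the degenerate and error cases", {
  expect_equal(rmse_ratio(0.3, 0.3), 1)
  expect_equal(rmse_ratio(0.3, 0.6), 0.5)
  expect_equal(rmse_ratio(0, 0), 1)
  expect_error(rmse_ratio(0.2, 0), "impossible")
})

test_that("downstream sets follow directed hyper-edge reachability", {
  chain <- mk_bn(c("a", "b", "c"), b = list(c(a = 1)), c = list(c(b = 1)))
  expect_setequal(downstream_set(chain, "a"), c("b", "c"))
  expect_equal(downstream_set(chain, "c"), character(0))
  cyc <- mk_bn(c("a", "b"), b = list(c(a = 1)), a = list(c(b = 1)))
  expect_equal(downstream_set(cyc, "a"), "b") # root excluded even in a cycle
  expect_error(downstream_set(chain, "zz"), "unknown root")
  # works on a PKN too
  net <- pkn(tibble::tibble(source = c("s", "x"), sign = 1L, target = c("x", "y")))
  expect_setequal(downstream_set(net, "s"), c("x", "y"))
})

test_that("tpr_fpr computes the set-count rates", {
  uni <- paste0("n", 1:10)
  std <- uni[1:4]
  inf <- c(uni[1:3], uni[5:6])
  r <- tpr_fpr(std, inf, uni)
  expect_equal(r$tpr, 3 / 4)
  expect_equal(r$fpr, 2 / 6)
  expect_equal(tpr_fpr(std, std, uni), tibble::tibble(tpr = 1, fpr = 0))
  expect_equal(tpr_fpr(std, uni, uni), tibble::tibble(tpr = 1, fpr = 1))
  expect_equal(tpr_fpr(std, character(0), uni), tibble::tibble(tpr = 0, fpr = 0))
  expect_error(tpr_fpr(character(0), inf, uni), "empty standard")
  expect_error(tpr_fpr(uni, inf, uni), "universe equals")
})

test_that("family_auroc integrates the anchored upper envelope", {
  expect_equal(family_auroc(tibble::tibble(fpr = 0, tpr = 1)), 1)
  expect_equal(family_auroc(tibble::tibble(fpr = 0.5, tpr = 0.5)), 0.5)
  # trapezoid through (0,0)-(0.2,0.8)-(1,1)
  expect_equal(family_auroc(tibble::tibble(fpr = 0.2, tpr = 0.8)), 0.80)
  # invariant to duplication and order
  pts <- tibble::tibble(fpr = c(0.2, 0.6, 0.4), tpr = c(0.5, 0.9, 0.7))
  a1 <- family_auroc(pts)
  a2 <- family_auroc(pts[c(3, 1, 2, 2, 1), ])
  expect_equal(a1, a2)
  # duplicate fpr keeps the best tpr (upper envelope)
  env <- family_auroc(tibble::tibble(fpr = c(0.3, 0.3), tpr = c(0.2, 0.9)))
  expect_equal(env, family_auroc(tibble::tibble(fpr = 0.3, tpr = 0.9)))
})

test_that("node centrality matches the connected-pair betweenness convention", {
  chain <- mk_bn(c("a", "b", "c"), b = list(c(a = 1)), c = list(c(b = 1)))
  expect_equal(node_centrality(chain, "b"), 1)
  expect_equal(node_centrality(chain, "c"), 0) # sink leaf
  expect_error(node_centrality(chain, "zz"), "unknown node")
  # hub of a directed star is maximal
  star <- mk_bn(
    c("i1", "i2", "h", "o1", "o2"),
    h = list(c(i1 = 1), c(i2 = 1)),
    o1 = list(c(h = 1)), o2 = list(c(h = 1))
  )
  cents <- vapply(star$nodes, function(nd) node_centrality(star, nd), numeric(1))
  expect_equal(names(which.max(cents)), "h")
})

test_that("random validation is exact on self-generated data and spec-shaped", {
  cfg <- sim_config(
    n_nodes = 7L, n_stimuli = 2L, n_inhibitors = 1L, n_readouts = 3L,
    n_perturbations = 3L, k_timepoints = 4L, noise_sd = 0, seed = 13L
  )
  net <- generate_pkn(cfg)
  bn0 <- sample_true_bn(net, seed = 13L)
  raw <- simulate_dataset(bn0, net, cfg)
  norm <- normalize(raw)
  fam <- bn_family(list(bn0))
  # structured data: the generating network reproduces its own binarized data
  self_fit <- family_best_fit(fam, norm, net$roles)
  expect_equal(rmse_ratio(self_fit$discrete_rmse, self_fit$model_rmse), 1)
  # n_samples = 0 gives an empty, well-typed distribution
  rv0 <- random_validation(fam, norm, net$roles, n_samples = 0)
  expect_equal(nrow(rv0), 0L)
  rv <- random_validation(fam, norm, net$roles, n_samples = 8, seed = 2)
  expect_equal(nrow(rv), 8L)
  expect_true(all(rv$ratio <= 1 + 1e-12))
  # seeded reproducibility
  rv2 <- random_validation(fam, norm, net$roles, n_samples = 8, seed = 2)
  expect_equal(rv$ratio, rv2$ratio)
})
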