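test_that("successors implement the any-subset update schedule", {
  bn <- boolean_network(c("a", "b"), list(a = list(c(b = 1)), b = list(c(a = 1))))
  succ <- successors(bn, c(a = 0, b = 1))
  keys <- sort(vapply(succ, paste, character(1), collapse = ""))
  expect_equal(keys, sort(c("11", "00", "10")))
  # fixpoint has no successors
  fix <- boolean_network(c("a"), list(a = list(c(a = 1))))
  expect_length(successors(fix, c(a = 1)), 0L)
  # clamped nodes never change, and x must respect the clamp
  expect_error(
    successors(bn, c(a = 0, b = 1), clamp = c(a = 1)),
    "clamping"
  )
  s2 <- successors(bn, c(a = 0, b = 1), clamp = c(b = 1))
  expect_equal(vapply(s2, paste, character(1), collapse = ""), "11")
})

test_that("successors agree with the brute-force oracle on random networks", {
  for (seed in 1:12) {
    n <- sample(2:5, 1)
    bn <- random_test_bn(n, seed)
    x <- setNames(sample(0:1, n, replace = TRUE), bn$nodes)
    got <- sort(vapply(successors(bn, x), paste, character(1), collapse = ""))
    want <- sort(unique(vapply(
      oracle_successors(bn, x), function(s) paste(s[bn$nodes], collapse = ""),
      character(1)
    )))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("synchronous and asynchronous steps are sub-relations of successors", {
  for (seed in 13:18) {
    bn <- random_test_bn(4, seed)
    x <- setNames(sample(0:1, 4, replace = TRUE), bn$nodes)
    fx <- oracle_eval(bn, x)
    succ <- vapply(successors(bn, x), paste, character(1), collapse = "")
    if (any(fx != x)) {
      # synchronous image (all nodes at once)
      expect_true(paste(fx, collapse = "") %in% succ)
      # each asynchronous single-node update
      for (nd in bn$nodes[fx != x]) {
        y <- x
        y[nd] <- fx[nd]
        expect_true(paste(y, collapse = "") %in% succ)
      }
    }
  }
})

test_that("reachable answers the base reachability cases", {
  # reflexivity: goal equal to start
  bn <- boolean_network(c("a", "b"), list(a = list(c(b = 1))))
  expect_true(reachable(bn, c(a = 0, b = 0), c(a = 0, b = 0)))
  # one-step negation flip
  neg <- boolean_network(c("a", "b"), list(a = list(c(a = -1))))
  expect_true(reachable(neg, c(a = 0, b = 0), c(a = 1)))
  # unregulated b stays 0, so a <- b can never fire
  dep <- boolean_network(c("a", "b"), list(a = list(c(b = 1))))
  expect_false(reachable(dep, c(a = 0, b = 0), c(a = 1)))
  # unknown goal node
  expect_error(reachable(dep, c(a = 0, b = 0), c(z = 1)), "unknown node")
})

test_that("reachable matches the explicit-graph oracle and reports budgets", {
  for (seed in 19:30) {
    n <- sample(2:5, 1)
    bn <- random_test_bn(n, seed)
    x <- setNames(sample(0:1, n, replace = TRUE), bn$nodes)
    y <- setNames(sample(0:1, n, replace = TRUE), bn$nodes)
    expect_equal(
      reachable(bn, x, y),
      oracle_reachable(bn, x, y),
      info = paste("seed", seed)
    )
  }
  # exhausting a tiny budget is NA, never FALSE
  chain <- boolean_network(
    paste0("c", 1:4),
    list(
      c2 = list(c(c1 = 1)), c3 = list(c(c2 = 1)), c4 = list(c(c3 = 1))
    )
  )
  x <- c(c1 = 1, c2 = 0, c3 = 0, c4 = 0)
  expect_true(is.na(reachable(chain, x, c(c4 = 1), budget = 2)))
  expect_true(reachable(chain, x, c(c4 = 1)))
})

test_that("meta_successors widen one component at a time", {
  bn <- boolean_network(c("a", "b"), list(a = list(c(b = 1))))
  # fully widened meta-state cannot grow
  expect_length(meta_successors(bn, c(a = "*", b = "*")), 0L)
  # image of f_a over u = ({0},{1}) is {1}: component a widens
  succ <- meta_successors(bn, c(a = "0", b = "1"))
  expect_length(succ, 1L)
  expect_equal(succ[[1]], c(a = "*", b = "1"))
  # clamped components are never widened
  expect_length(meta_successors(bn, c(a = "0", b = "1"), clamp = c(a = 0, b = 1)), 0L)
})

test_that("support consistency is reflexive and implied by reachability", {
  bn <- boolean_network(c("a", "b"), list(a = list(c(b = 1))))
  x <- c(a = 0, b = 1)
  expect_true(support_consistent(bn, x, x))
  # soundness on random networks: exact reachability implies support
  # consistency (never the contrapositive violation)
  for (seed in 31:45) {
    n <- sample(2:5, 1)
    bnr <- random_test_bn(n, seed)
    x <- setNames(sample(0:1, n, replace = TRUE), bnr$nodes)
    for (y in all_states(bnr$nodes)) {
      if (oracle_reachable(bnr, x, y)) {
        expect_true(support_consistent(bnr, x, y),
          info = paste("seed", seed, paste(y, collapse = ""))
        )
      }
    }
  }
})

test_that("the over-approximation admits a false positive on 3 nodes", {
  # b <- c, c <- !b & c: from (b,c) = (1,1) the only runs are
  # (1,1) -> (1,0) -> (0,0); (b=0, c=1) is support-consistent but unreachable
  bn <- boolean_network(
    c("a", "b", "c"),
    list(b = list(c(c = 1)), c = list(c(b = -1, c = 1)))
  )
  x <- c(a = 0, b = 1, c = 1)
  y <- c(a = 0, b = 0, c = 1)
  expect_true(support_consistent(bn, x, y))
  expect_false(reachable(bn, x, y))
  expect_false(oracle_reachable(bn, x, y))
})

test_that("meta-state chains from a singleton have length at most n", {
  for (seed in 46:51) {
    n <- sample(2:6, 1)
    bn <- random_test_bn(n, seed)
    cp <- bnfit:::compile_bn(bn)
    x <- sample(0L:(2^n - 1L), 1L)
    clo <- bnfit:::meta_closure(cp, x, 0L, 0L)
    widened <- vapply(clo$Ws, bnfit:::popcount, integer(1))
    expect_true(all(widened <= n))
    expect_true(0L %in% clo$Ws) # zero-step closure contains the singleton
  }
})
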