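# Independent brute-force oracles, written against the user-level (named
# vector) representation and plain R data structures, deliberately avoiding
# the package's packed-integer internals.

oracle_eval <- function(bn, x) {
  vapply(bn$nodes, function(nd) {
    cls <- bn$functions[[nd]]
    if (length(cls) == 0L) return(as.integer(x[[nd]]))
    for (cl in cls) {
      vals <- x[names(cl)]
      if (all(ifelse(cl > 0L, vals == 1L, vals == 0L))) return(1L)
    }
    0L
  }, integer(1))
}

oracle_successors <- function(bn, x, clamp = NULL) {
  fx <- oracle_eval(bn, x)
  free <- setdiff(bn$nodes, names(clamp))
  changed <- intersect(free, bn$nodes[fx != x[bn$nodes]])
  out <- list()
  if (length(changed) == 0L) return(out)
  for (sz in seq_along(changed)) {
    for (sub in utils::combn(changed, sz, simplify = FALSE)) {
      y <- x
      y[sub] <- fx[sub]
      out[[length(out) + 1L]] <- y
    }
  }
  out
}

oracle_reachable <- function(bn, x, goal, clamp = NULL) {
  key <- function(s) paste(s[bn$nodes], collapse = "")
  matches <- function(s) all(s[names(goal)] == goal)
  seen <- new.env(parent = emptyenv())
  queue <- list(x)
  assign(key(x), TRUE, envir = seen)
  while (length(queue) > 0L) {
    s <- queue[[1L]]
    queue <- queue[-1L]
    if (matches(s)) return(TRUE)
    for (y in oracle_successors(bn, s, clamp)) {
      k <- key(y)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        queue <- c(queue, list(y))
      }
    }
  }
  FALSE
}

# All states over `nodes` as named 0/1 vectors.
all_states <- function(nodes) {
  grid <- expand.grid(rep(list(0:1), length(nodes)))
  lapply(seq_len(nrow(grid)), function(i) {
    stats::setNames(as.integer(grid[i, ]), nodes)
  })
}

# Random Boolean network over n nodes for property tests (independent of the
# synthetic module).
random_test_bn <- function(n, seed) {
  set.seed(seed)
  nodes <- paste0("n", seq_len(n))
  fns <- list()
  for (i in seq_len(n)) {
    d <- sample(0:min(3L, n), 1L)
    if (d == 0L) next
    regs <- sample(nodes, d)
    cls <- list()
    for (j in seq_len(sample(1:2, 1L))) {
      sz <- sample.int(min(2L, d), 1L)
      rs <- sample(regs, sz)
      cls[[j]] <- stats::setNames(sample(c(-1L, 1L), sz, replace = TRUE), rs)
    }
    printed <- vapply(cls, function(cl) {
      cl <- cl[order(names(cl))]
      paste0(ifelse(cl < 0, "!", ""), names(cl), collapse = "&")
    }, character(1))
    fns[[nodes[i]]] <- cls[!duplicated(printed)]
  }
  boolean_network(nodes, fns)
}

# Independent exhaustive learner: enumerates every candidate network (each
# node choosing any subset of its clause space up to the caps) and, for each,
# every trace via full dynamic programming over all clamp-consistent states,
# with support_consistent() as the step relation. Returns the global minimum
# sum of squared errors (excess over nothing — absolute).
brute_force_learn <- function(net, data, max_clause_size = 2L,
                              max_clauses_per_node = 2L, threshold = 0.5) {
  cs <- clause_space(net, max_clause_size)
  nodes <- net$nodes
  per_node <- lapply(nodes, function(nd) {
    tbl <- cs[cs$target == nd, ]
    opts <- list(list())
    if (nrow(tbl) > 0L) {
      for (sz in seq_len(min(nrow(tbl), max_clauses_per_node))) {
        for (ix in utils::combn(nrow(tbl), sz, simplify = FALSE)) {
          opts <- c(opts, list(tbl$literals[ix]))
        }
      }
    }
    opts
  })
  perts <- pts_perturbations(data)
  timepoints <- pts_timepoints(data)
  observed <- pts_observed(data)
  k <- length(timepoints)
  grid_idx <- expand.grid(lapply(per_node, seq_along))
  best <- Inf
  for (gi in seq_len(nrow(grid_idx))) {
    fns <- list()
    for (i in seq_along(nodes)) {
      opt <- per_node[[i]][[grid_idx[gi, i]]]
      if (length(opt) > 0L) fns[[nodes[i]]] <- opt
    }
    bn <- boolean_network(nodes, fns)
    tot <- 0
    feasible <- TRUE
    for (p in perts) {
      cl <- clamping(pts_settings(data, p), net$roles)
      states <- Filter(
        function(s) length(cl) == 0L || all(s[names(cl)] == cl),
        all_states(nodes)
      )
      mm <- data$measurements[data$measurements$perturbation == p, ]
      layer_cost <- function(s, j) {
        tv <- mm$value[match(paste(timepoints[j], observed), paste(mm$time, mm$node))]
        sum((tv - s[observed])^2)
      }
      ns <- length(states)
      scmat <- matrix(FALSE, ns, ns)
      for (si in seq_len(ns)) {
        for (ti in seq_len(ns)) {
          scmat[si, ti] <- support_consistent(bn, states[[si]], states[[ti]], cl)
        }
      }
      dp <- vapply(states, layer_cost, numeric(1), j = 1L)
      for (j in seq_len(k - 1L)) {
        dp2 <- rep(Inf, ns)
        for (ti in seq_len(ns)) {
          feas <- dp[scmat[, ti]]
          if (length(feas) > 0L && any(is.finite(feas))) {
            dp2[ti] <- min(feas) + layer_cost(states[[ti]], j + 1L)
          }
        }
        dp <- dp2
      }
      if (!any(is.finite(dp))) {
        feasible <- FALSE
        break
      }
      tot <- tot + min(dp)
    }
    if (feasible && tot < best) best <- tot
  }
  ncells <- length(observed) * k * length(perts)
  sqrt(best / ncells)
}

# Small random learning instance shared by optimality tests.
random_instance <- function(seed, n_nodes = 3L, n_perts = 2L, k = 3L) {
  set.seed(seed)
  nodes <- paste0("g", seq_len(n_nodes))
  stim <- nodes[1]
  n_edges <- sample(2:4, 1L)
  src <- sample(nodes, n_edges, replace = TRUE)
  tgt <- sample(setdiff(nodes, stim), n_edges, replace = TRUE)
  ok <- src != tgt
  edges <- unique(data.frame(
    source = c(src[ok], stim), # ensure the stimulus is in the network
    sign = c(sample(c(1L, -1L), sum(ok), replace = TRUE), 1L),
    target = c(tgt[ok], nodes[2])
  ))
  present <- unique(c(edges$source, edges$target))
  reads <- setdiff(present, stim)
  net <- pkn(edges, roles = c(
    stats::setNames("stimulus", stim),
    stats::setNames(rep("readout", length(reads)), reads)
  ))
  rows <- list()
  pert_rows <- list()
  for (pi in seq_len(n_perts)) {
    pid <- sprintf("p%02d", pi)
    pert_rows[[pi]] <- tibble::tibble(
      perturbation = pid, node = stim, value = sample(0:1, 1L)
    )
    rows[[pi]] <- tibble::tibble(
      perturbation = pid,
      time = rep(seq_len(k) * 10, each = length(reads)),
      node = rep(reads, k),
      value = round(runif(k * length(reads)), 3)
    )
  }
  data <- pert_ts(dplyr::bind_rows(rows), dplyr::bind_rows(pert_rows))
  # max-normalize so the learner's precondition holds
  data <- normalize(data)
  list(net = net, data = data)
}
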