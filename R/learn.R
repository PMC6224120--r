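#' Root mean square error between measurements and binary traces
#'
#' The objective the learner minimizes: over all observed nodes, time points
#' and perturbations, `sqrt(mean((t - y)^2))` with `t` the normalized
#' measurement and `y` the 0/1 trace value; the normalizer is the full
#' `m * k * |P|` grid.
#'
#' @param observed A normalized `pert_ts`.
#' @param predicted Predicted 0/1 values: a binarized `pert_ts` or a data
#'   frame with columns `perturbation`, `time`, `node`, `value` covering
#'   exactly the same grid.
#' @return A single RMSE value.
#' @export
rmse <- function(observed, predicted) {
  validate_pert_ts(observed, allow_missing = FALSE)
  pv <- if (inherits(predicted, "pert_ts")) predicted$measurements else as_tibble(predicted)
  keys <- c("perturbation", "time", "node")
  om <- observed$measurements
  if (nrow(pv) != nrow(om) ||
    nrow(dplyr::anti_join(om, pv, by = keys)) > 0L) {
    stop("observed and predicted grids do not match", call. = FALSE)
  }
  j <- left_join(om, pv, by = keys, suffix = c("", "_pred"))
  if (!all(j$value_pred %in% c(0, 1))) stop("predicted values must be 0/1", call. = FALSE)
  sqrt(mean((j$value - j$value_pred)^2))
}

#' Discretization error floor
#'
#' The RMSE between a normalized dataset and its own binarization — the floor
#' no binary-valued fit can beat under the chosen threshold.
#'
#' @inheritParams rmse
#' @param threshold Binarization cutoff, as in [binarize()].
#' @return A single RMSE value.
#' @export
discrete_rmse <- function(observed, threshold = 0.5) {
  rmse(observed, binarize(observed, threshold))
}

#' Learner configuration
#'
#' @param max_clause_size Clause size cap for the candidate space (default 2).
#' @param max_clauses_per_node Cap on clauses per node in a candidate network
#'   (default 3).
#' @param max_models Maximum number of optimal networks returned (default
#'   200); enumeration of co-optimal models stops there and the result is
#'   flagged truncated.
#' @param max_candidates Cap on the number of candidate networks examined.
#'   When the search proves its incumbent equal to the discretization floor the
#'   result is globally optimal regardless of this cap; otherwise optimality
#'   is only proven if the space was exhausted within the cap.
#' @param order `"heuristic"` (candidate functions ordered by a local
#'   transition-fit score, so promising networks are enumerated first) or
#'   `"canonical"` (plain lexicographic order over the clause space).
#' @param trace_budget Cap on priority-queue pops per perturbation in the
#'   trace search.
#' @param seed Stored in the run manifest; the search itself is deterministic.
#' @return A list of class `learn_config`.
#' @export
learn_config <- function(max_clause_size = 2L, max_clauses_per_node = 3L,
                         max_models = 200L, max_candidates = 20000L,
                         order = c("heuristic", "canonical"),
                         trace_budget = 20000L, seed = 1L) {
  stopifnot(
    max_clause_size >= 1L, max_clauses_per_node >= 1L, max_models >= 1L,
    max_candidates >= 1L, trace_budget >= 1L
  )
  structure(list(
    max_clause_size = as.integer(max_clause_size),
    max_clauses_per_node = as.integer(max_clauses_per_node),
    max_models = as.integer(max_models),
    max_candidates = as.integer(max_candidates),
    order = match.arg(order),
    trace_budget = as.integer(trace_budget),
    seed = as.integer(seed)
  ), class = "learn_config")
}

# Candidate function options for one node: all subsets (including the empty
# set = identity) of its clause space, up to max_clauses_per_node, in
# canonical order (number of clauses, then lexicographic clause ids).
node_options <- function(clause_ids, max_clauses) {
  opts <- list(integer(0))
  for (s in seq_len(min(length(clause_ids), max_clauses))) {
    opts <- c(opts, combn(clause_ids, s, simplify = FALSE))
  }
  opts
}

# Local transition-fit score of one node option against binarized pseudo-states
# (used only to order enumeration, never to exclude candidates). bstates is a
# list per perturbation of k packed states; target_bit the node's bit.
option_score <- function(clauses_masks, bstates, target_bit, full) {
  eval1 <- function(z) {
    for (cl in clauses_masks) {
      if (bitwAnd(z, cl$pos) == cl$pos && bitwAnd(z, cl$neg) == 0L) return(1L)
    }
    0L
  }
  pen <- 0L
  for (bs in bstates) {
    k <- length(bs)
    if (k < 2L) next
    for (j in seq_len(k - 1L)) {
      v0 <- as.integer(bitwAnd(bs[j], target_bit) != 0L)
      v1 <- as.integer(bitwAnd(bs[j + 1L], target_bit) != 0L)
      if (length(clauses_masks) == 0L) {
        # identity keeps the value: penalize observed changes
        if (v0 != v1) pen <- pen + 1L
      } else if (v0 == v1) {
        if (eval1(bs[j]) != v0) pen <- pen + 1L
      } else {
        if (eval1(bs[j]) != v1 && eval1(bs[j + 1L]) != v1) pen <- pen + 1L
      }
    }
  }
  pen
}

# Shared machinery of learn(), family_best_fit() and random_validation():
# the per-perturbation trace-fitting problem and its uniform-cost search.
#
# trace_problem() precomputes, for every perturbation: the clamping, the
# candidate full states (free bits expanded over the clamp), the per-time-point
# continuous cost of every state, and the discretization floor. Costs are
# expressed as *excess over the floor*, so a zero-excess trace is provably
# globally optimal.
trace_problem <- function(nodes, data, roles, threshold = 0.5) {
  validate_pert_ts(data, allow_missing = FALSE)
  n <- length(nodes)
  bits <- bit_masks(n)
  full <- full_mask(n)
  perts <- pts_perturbations(data)
  timepoints <- pts_timepoints(data)
  observed <- pts_observed(data)
  k <- length(timepoints)
  m <- length(observed)
  obs_bits <- bits[match(observed, nodes)]
  bin <- binarize(data, threshold)
  prep <- lapply(perts, function(p) {
    cl <- clamping(pts_settings(data, p), roles)
    pcl <- pack_clamp(cl, nodes)
    freebits <- bits[bitwAnd(pcl$mask, bits) == 0L]
    if (length(freebits) > 16L) {
      stop("more than 16 unclamped nodes; this explicit-state trace search targets desk-scale problems",
        call. = FALSE
      )
    }
    states <- pcl$value
    for (b in freebits) states <- c(states, states + b)
    mm <- data$measurements[data$measurements$perturbation == p, ]
    bb <- bin$measurements[bin$measurements$perturbation == p, ]
    cost <- matrix(0, nrow = length(states), ncol = k)
    floors <- numeric(k)
    bstate <- integer(k)
    for (j in seq_len(k)) {
      tv <- mm$value[match(paste(timepoints[j], observed), paste(mm$time, mm$node))]
      c0 <- tv^2
      c1 <- (1 - tv)^2
      lc <- numeric(length(states))
      for (ii in seq_len(m)) {
        on <- bitwAnd(states, obs_bits[ii]) != 0L
        lc <- lc + ifelse(on, c1[ii], c0[ii])
      }
      cost[, j] <- lc
      floors[j] <- sum(pmin(c0, c1))
      bv <- bb$value[match(paste(timepoints[j], observed), paste(bb$time, bb$node))]
      bstate[j] <- bitwOr(pcl$value, as.integer(sum(obs_bits[bv == 1])))
    }
    excess <- sweep(cost, 2L, floors)
    excess[abs(excess) < 1e-12] <- 0
    list(
      id = p, clampmask = pcl$mask, clampval = pcl$value, states = states,
      excess = excess, floor = sum(floors), bstates = bstate,
      # per-time-point state order by increasing excess (search expansion order)
      ord = lapply(seq_len(k), function(j) order(excess[, j])),
      # excess of the best constant trace: a universal feasible upper bound,
      # since support consistency is reflexive
      const_ub = min(rowSums(excess))
    )
  })
  list(
    perts = prep, floor_sq = sum(vapply(prep, `[[`, numeric(1), "floor")),
    ncells = m * k * length(perts), k = k, m = m, observed = observed,
    timepoints = timepoints, bin = bin, full = full
  )
}

# Uniform-cost search over (time point, state) for one perturbation: an edge
# into (j+1, s') exists iff s' is support-consistent with s under the clamp;
# node cost is the state's excess over the floor at its time point. Returns
# the minimal total excess (Inf if above `cap` or the pop budget) and the
# argmin state path.
trace_search <- function(cp, pp, cap, k, trace_budget = 20000L) {
  ns <- length(pp$states)
  # the best constant trace is always feasible, so the search never needs to
  # look above it (and never returns Inf unless capped below it)
  cap <- min(cap, pp$const_ub + 1e-12)
  g <- matrix(Inf, nrow = ns, ncol = k)
  parent <- matrix(NA_integer_, nrow = ns, ncol = k)
  qg <- pp$excess[, 1L]
  qs <- seq_len(ns)
  qj <- rep(1L, ns)
  keep <- qg <= cap + 1e-9
  qg <- qg[keep]
  qs <- qs[keep]
  qj <- qj[keep]
  g[cbind(qs, qj)] <- qg
  pops <- 0L
  # per-call caches of the widening fixpoint and (rarely) the full closure per
  # source state; the clamping is fixed within one call
  ws_cache <- vector("list", cp$full + 1L)
  clo_cache <- vector("list", cp$full + 1L)
  while (length(qg) > 0L) {
    i <- which.min(qg)
    cg <- qg[i]
    csi <- qs[i]
    cj <- qj[i]
    qg <- qg[-i]
    qs <- qs[-i]
    qj <- qj[-i]
    if (cg > g[csi, cj] + 1e-12) next # stale queue entry
    if (cj == k) {
      return(list(excess = cg, path = trace_unwind(parent, csi, k), pops = pops))
    }
    pops <- pops + 1L
    if (pops > trace_budget) return(list(excess = Inf, path = NULL, pops = pops))
    nj <- cj + 1L
    # batch the affordable, improvable targets (states sorted by excess)
    tis <- integer(0)
    for (ti in pp$ord[[nj]]) {
      ng <- cg + pp$excess[ti, nj]
      if (ng > cap + 1e-9) break
      if (ng < g[ti, nj] - 1e-12) tis <- c(tis, ti)
    }
    if (length(tis) == 0L) next
    x <- pp$states[csi]
    ys <- pp$states[tis]
    ws <- ws_cache[[x + 1L]]
    if (is.null(ws)) {
      ws <- greedy_wstar(cp, x, pp$clampmask)
      ws_cache[[x + 1L]] <- ws
    }
    diff <- bitwXor(x, ys)
    possible <- bitwAnd(diff, bitwXor(cp$full, ws$W)) == 0L
    same <- bitwXor(diff, cp$full)
    image_ok <- bitwOr(
      bitwAnd(ys, ws$img1),
      bitwAnd(bitwXor(ys, cp$full), ws$img0)
    )
    fail <- bitwAnd(bitwAnd(same, ws$W), bitwXor(cp$full, image_ok))
    ok <- possible & fail == 0L
    todo <- which(possible & fail != 0L)
    if (length(todo) > 0L) {
      clo <- clo_cache[[x + 1L]]
      if (is.null(clo)) {
        clo <- meta_closure(cp, x, pp$clampmask, pp$clampval)
        clo_cache[[x + 1L]] <- clo
      }
      ok[todo] <- sc_check_many(clo, cp$full, ys[todo])
    }
    for (ii in which(ok)) {
      ti <- tis[ii]
      ng <- cg + pp$excess[ti, nj]
      g[ti, nj] <- ng
      parent[ti, nj] <- csi
      qg <- c(qg, ng)
      qs <- c(qs, ti)
      qj <- c(qj, nj)
    }
  }
  list(excess = Inf, path = NULL, pops = pops)
}

trace_unwind <- function(parent, last, k) {
  path <- integer(k)
  path[k] <- last
  for (j in rev(seq_len(k - 1L))) path[j] <- parent[path[j + 1L], j + 1L]
  path
}

#' Learn RMSE-optimal Boolean networks from perturbation time series
#'
#' Complete optimizing search over the product of (a) candidate networks from
#' the PKN's sign-consistent clause space and (b) binary traces assigning one
#' full network state to each observed time point. Traces must respect each
#' perturbation's clamping, consecutive states must be support-consistent
#' (the over-approximation of reachability), unobserved components are chosen
#' existentially, and the objective is the RMSE between the data and the trace
#' restricted to observed nodes. Data points where the optimal trace disagrees
#' with the binarized data are the automatically corrected (penalized) points.
#'
#' Each candidate's best trace is found by a uniform-cost search over
#' per-time-point states with the accumulated excess over the discretization
#' floor as cost; a candidate is abandoned as soon as its partial excess
#' exceeds the incumbent. When the candidate space fits within
#' `max_candidates` it is enumerated exhaustively (branch-and-bound), which
#' proves global optimality by completeness. Larger spaces are searched by
#' deterministic coordinate descent from a heuristically ordered starting
#' assignment, followed by a clustered enumeration of co-optimal neighbours;
#' an incumbent with zero excess equals the discretization floor — a proven
#' global lower bound — so optimality is still certified in that case, and
#' `proven_optimal` reports whether either certificate holds.
#'
#' @param x A `pkn`.
#' @param data A normalized, QC'd `pert_ts` (no missing values; every treated
#'   or observed node present in the PKN).
#' @param config A [learn_config()].
#' @param threshold Binarization threshold used for the floor, penalized
#'   points and corrected data.
#' @return An object of class `bn_learn`: a list with `results` (list of
#'   `bn_fit` objects sharing the minimal objective), `objective` (model
#'   RMSE), `discrete_rmse`, `proven_optimal`, `truncated`, `n_candidates`
#'   (examined), and `config`. Each `bn_fit` holds `bn`, `traces` (per
#'   perturbation a k x n 0/1 state matrix), `model_rmse`, `discrete_rmse`,
#'   `penalized_points` (tibble), and `corrected` (binarized `pert_ts` equal
#'   to the trace restricted to observed nodes).
#' @export
learn <- function(x, data, config = learn_config(), threshold = 0.5) {
  stopifnot(inherits(x, "pkn"), inherits(config, "learn_config"))
  validate_pert_ts(data, allow_missing = FALSE)
  if (data$binarized) stop("`data` must be normalized, not binarized", call. = FALSE)

  nodes <- x$nodes
  missing_nodes <- setdiff(
    c(unique(data$perturbations$node), pts_observed(data)), nodes
  )
  if (length(missing_nodes) > 0L) {
    stop("dataset node(s) absent from the PKN: ",
      paste(missing_nodes, collapse = ", "),
      call. = FALSE
    )
  }
  n <- length(nodes)
  bits <- bit_masks(n)
  full <- full_mask(n)

  cs <- clause_space(x, config$max_clause_size)
  if (nrow(cs) == 0L) {
    stop("empty candidate space: the PKN admits no clauses", call. = FALSE)
  }

  tp <- trace_problem(nodes, data, x$roles, threshold)
  prep <- tp$perts
  k <- tp$k
  observed <- tp$observed
  timepoints <- tp$timepoints
  bin <- tp$bin
  ncells <- tp$ncells
  floor_sq <- tp$floor_sq
  disc <- sqrt(floor_sq / ncells)

  # ---- candidate space ----
  cs_by_node <- split(cs, cs$target)
  opt_list <- list()
  for (nd in nodes) {
    tbl <- cs_by_node[[nd]]
    if (is.null(tbl)) {
      opt_list[[nd]] <- list(integer(0))
    } else {
      opt_list[[nd]] <- node_options(tbl$clause_id, config$max_clauses_per_node)
    }
  }
  # masks per clause for scoring
  clause_masks <- function(nd, ids) {
    tbl <- cs_by_node[[nd]]
    lapply(ids, function(id) {
      lit <- tbl$literals[[match(id, tbl$clause_id)]]
      idx <- match(names(lit), nodes)
      list(
        pos = as.integer(sum(bits[idx[lit > 0L]])),
        neg = as.integer(sum(bits[idx[lit < 0L]]))
      )
    })
  }
  if (config$order == "heuristic") {
    bstates <- lapply(prep, `[[`, "bstates")
    for (nd in nodes) {
      opts <- opt_list[[nd]]
      if (length(opts) <= 1L) next
      sc <- vapply(opts, function(ids) {
        option_score(clause_masks(nd, ids), bstates, bits[match(nd, nodes)], full)
      }, integer(1))
      opt_list[[nd]] <- opts[order(sc)] # stable: canonical order breaks ties
    }
  }
  counts <- lengths(opt_list)
  space_size <- prod(as.numeric(counts))

  build_candidate <- function(idx) {
    fns <- list()
    for (i in seq_len(n)) {
      ids <- opt_list[[i]][[idx[i]]]
      if (length(ids) == 0L) next
      tbl <- cs_by_node[[nodes[i]]]
      fns[[nodes[i]]] <- tbl$literals[match(ids, tbl$clause_id)]
    }
    boolean_network(nodes, fns)
  }

  # ---- search over candidates ----
  # Evaluate one candidate assignment: the sum over perturbations of the
  # minimal trace excess, abandoned as soon as it exceeds `cap`.
  examined <- 0
  eval_candidate <- function(idx, cap) {
    examined <<- examined + 1
    bn <- build_candidate(idx)
    cp <- compile_bn(bn)
    tot <- 0
    paths <- vector("list", length(prep))
    for (pi in seq_along(prep)) {
      bt <- trace_search(cp, prep[[pi]], cap + 1e-9 - tot, k, config$trace_budget)
      if (!is.finite(bt$excess)) {
        return(list(feasible = FALSE, excess = Inf))
      }
      tot <- tot + bt$excess
      paths[[pi]] <- bt$path
    }
    list(feasible = TRUE, excess = tot, bn = bn, paths = paths)
  }

  best_excess <- Inf
  optima <- list()
  truncated <- FALSE
  exhausted <- FALSE

  if (space_size <= config$max_candidates) {
    # Exhaustive branch-and-bound in lexicographic order: global optimality
    # by complete enumeration.
    idx <- rep(1L, n)
    n_opt_seen <- 0L
    repeat {
      ev <- eval_candidate(idx, if (is.finite(best_excess)) best_excess else Inf)
      if (ev$feasible && ev$excess < best_excess - 1e-9) {
        best_excess <- ev$excess
        optima <- list(ev)
        n_opt_seen <- 1L
      } else if (ev$feasible && ev$excess <= best_excess + 1e-9) {
        n_opt_seen <- n_opt_seen + 1L
        if (length(optima) < config$max_models) {
          optima <- c(optima, list(ev))
        }
      }
      p <- n
      while (p >= 1L && idx[p] == counts[p]) {
        idx[p] <- 1L
        p <- p - 1L
      }
      if (p < 1L) {
        exhausted <- TRUE
        break
      }
      idx[p] <- idx[p] + 1L
    }
    truncated <- !exhausted || n_opt_seen > length(optima)
  } else {
    # The candidate space is too large to enumerate. Seed an incumbent by
    # deterministic coordinate descent from the heuristic-first assignment:
    # sweep the nodes, trying every alternative option for one node with the
    # others fixed, and move greedily. An incumbent with zero excess equals
    # the discretization floor and is therefore globally optimal even though
    # the space was not exhausted.
    idx <- rep(1L, n)
    ev <- eval_candidate(idx, Inf)
    best_excess <- ev$excess
    optima <- list(ev)
    sweeps <- 0L
    repeat {
      improved <- FALSE
      sweeps <- sweeps + 1L
      for (i in seq_len(n)) {
        if (best_excess <= 1e-9) break
        if (counts[i] <= 1L) next
        for (o in seq_len(counts[i])) {
          if (o == idx[i]) next
          idx2 <- idx
          idx2[i] <- o
          ev2 <- eval_candidate(idx2, best_excess)
          if (ev2$feasible && ev2$excess < best_excess - 1e-9) {
            idx <- idx2
            best_excess <- ev2$excess
            optima <- list(ev2)
            improved <- TRUE
            break # first improvement: move on, revisit on the next sweep
          }
          if (examined >= config$max_candidates) break
        }
        if (examined >= config$max_candidates) break
      }
      if (!improved || best_excess <= 1e-9 || sweeps >= 60L ||
        examined >= config$max_candidates) {
        break
      }
    }
    # Collect co-optimal models around the incumbent: per node, the options
    # that preserve the incumbent objective with all other nodes fixed, then
    # the lexicographic product of those options, each candidate re-verified
    # in full. This mirrors the clustered enumeration of co-optimal models.
    if (length(optima) > 0L && config$max_models > 1L &&
      examined < config$max_candidates) {
      co_opts <- vector("list", n)
      for (i in seq_len(n)) {
        keep_o <- idx[i]
        if (counts[i] > 1L) {
          for (o in seq_len(counts[i])) {
            if (o == idx[i]) next
            idx2 <- idx
            idx2[i] <- o
            ev2 <- eval_candidate(idx2, best_excess)
            if (ev2$feasible && ev2$excess <= best_excess + 1e-9) {
              keep_o <- c(keep_o, o)
            }
            if (examined >= config$max_candidates) break
          }
        }
        co_opts[[i]] <- sort(keep_o)
        if (examined >= config$max_candidates) break
      }
      if (all(lengths(co_opts) >= 1L)) {
        cidx <- rep(1L, n)
        ccounts <- lengths(co_opts)
        repeat {
          cand <- vapply(seq_len(n), function(i) co_opts[[i]][cidx[i]], integer(1))
          if (!identical(cand, idx)) {
            ev2 <- eval_candidate(cand, best_excess)
            if (ev2$feasible && ev2$excess <= best_excess + 1e-9 &&
              length(optima) < config$max_models) {
              optima <- c(optima, list(ev2))
            }
          }
          if (length(optima) >= config$max_models ||
            examined >= config$max_candidates) {
            break
          }
          p <- n
          while (p >= 1L && cidx[p] == ccounts[p]) {
            cidx[p] <- 1L
            p <- p - 1L
          }
          if (p < 1L) break
          cidx[p] <- cidx[p] + 1L
        }
      }
    }
    truncated <- TRUE
  }
  if (length(optima) == 0L || !is.finite(best_excess)) {
    stop("no candidate admits a support-consistent trace within the search budget",
      call. = FALSE
    )
  }
  proven <- exhausted || best_excess <= 1e-9

  results <- lapply(optima, function(opt) {
    make_bn_fit(
      opt, prep, nodes, observed, timepoints, bin, floor_sq, ncells, disc
    )
  })
  structure(list(
    results = results, objective = results[[1]]$model_rmse,
    discrete_rmse = disc, proven_optimal = proven, truncated = truncated,
    n_candidates = examined, space_size = space_size, config = config,
    threshold = threshold
  ), class = "bn_learn")
}

make_bn_fit <- function(opt, prep, nodes, observed, timepoints, bin,
                        floor_sq, ncells, disc) {
  k <- length(timepoints)
  traces <- list()
  pen <- list()
  corrected <- bin
  for (pi in seq_along(prep)) {
    pp <- prep[[pi]]
    sts <- pp$states[opt$paths[[pi]]]
    mat <- t(vapply(sts, unpack_state, integer(length(nodes)), nodes = nodes))
    rownames(mat) <- as.character(timepoints)
    traces[[pp$id]] <- mat
    # penalized points: trace vs binarized data on observed nodes
    for (j in seq_len(k)) {
      sel <- corrected$measurements$perturbation == pp$id &
        corrected$measurements$time == timepoints[j]
      bv <- corrected$measurements[sel, ]
      yv <- mat[j, observed]
      diffd <- observed[bv$value[match(observed, bv$node)] != yv]
      if (length(diffd) > 0L) {
        pen[[length(pen) + 1L]] <- tibble(
          perturbation = pp$id, time = timepoints[j], node = diffd
        )
      }
      corrected$measurements$value[sel] <-
        unname(yv[match(bv$node, observed)])
    }
  }
  penalized <- if (length(pen) > 0L) {
    bind_rows(pen)
  } else {
    tibble(perturbation = character(), time = numeric(), node = character())
  }
  structure(list(
    bn = opt$bn, traces = traces,
    model_rmse = sqrt((floor_sq + opt$excess) / ncells),
    discrete_rmse = disc,
    penalized_points = penalized, corrected = corrected
  ), class = "bn_fit")
}

#' @export
print.bn_learn <- function(x, ...) {
  cat(sprintf(
    "<bn_learn> %d optimal network(s); model RMSE %.4f (discrete floor %.4f)\n",
    length(x$results), x$objective, x$discrete_rmse
  ))
  cat(sprintf(
    "  examined %d of %.4g candidates; optimality %s%s\n",
    x$n_candidates, x$space_size,
    if (x$proven_optimal) "proven" else "not proven",
    if (x$truncated) "; enumeration truncated" else ""
  ))
  invisible(x)
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf(
    "<bn_fit> model RMSE %.4f, discrete RMSE %.4f, %d corrected point(s)\n",
    x$model_rmse, x$discrete_rmse, nrow(x$penalized_points)
  ))
  print(x$bn)
  invisible(x)
}

#' Tidy a learner run into one row per optimal network
#'
#' @param x A `bn_learn` object.
#' @param ... Unused.
#' @export
tidy.bn_learn <- function(x, ...) {
  tibble(
    model = seq_along(x$results),
    model_rmse = map_dbl(x$results, "model_rmse"),
    discrete_rmse = map_dbl(x$results, "discrete_rmse"),
    n_hyperedges = map_int(x$results, ~ nrow(bn_hyperedges(.x$bn))),
    n_penalized = map_int(x$results, ~ nrow(.x$penalized_points))
  )
}

#' @rdname tidy.bn_learn
#' @export
glance.bn_learn <- function(x, ...) {
  tibble(
    n_models = length(x$results),
    objective = x$objective,
    discrete_rmse = x$discrete_rmse,
    rmse_ratio = rmse_ratio(x$discrete_rmse, x$objective),
    proven_optimal = x$proven_optimal,
    truncated = x$truncated,
    n_candidates = x$n_candidates
  )
}
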