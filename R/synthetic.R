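#' Configuration for the synthetic benchmark generator
#'
#' The generator emulates the shape of multi-perturbation phosphoproteomic
#' screens — a handful of clamped stimuli/inhibitors, readouts measured on a
#' seven-point minute grid, a few hidden nodes — at desk scale, so that every
#' pipeline stage can be exercised without any external dataset.
#'
#' @param n_nodes Total nodes (default 10).
#' @param edge_density Probability of extra edges beyond the spanning
#'   structure (default 0.2).
#' @param n_stimuli,n_inhibitors,n_readouts Role counts; inhibitors are also
#'   measured (`inhibitor_and_readout`), mirroring real screens where the
#'   inhibited protein is on the readout panel. Remaining nodes are
#'   unobserved. `n_readouts = NULL` (default) measures every node except
#'   stimuli, inhibitors and one hidden node.
#' @param n_perturbations Number of perturbations (default 6).
#' @param k_timepoints Time points per series (default 7, on the canonical
#'   0/5/15/30/60/120/240 min grid when `k_timepoints == 7`).
#' @param noise_sd Gaussian noise added to the band-coded continuous signal
#'   (default 0.05; 0 makes binarization at 0.5 exact).
#' @param defects Character vector among `"missing_t0"`,
#'   `"duplicate_timepoint"`, `"inhibitor_dynamic"` — quality-control defects
#'   injected into the emitted dataset.
#' @param steps_max Maximum random walk steps between consecutive recorded
#'   time points (default 2).
#' @param seed Seed controlling all generator randomness.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_nodes = 10L, edge_density = 0.2, n_stimuli = 3L,
                       n_inhibitors = 1L, n_readouts = NULL,
                       n_perturbations = 6L, k_timepoints = 7L,
                       noise_sd = 0.05, defects = character(0),
                       steps_max = 2L, seed = 1L) {
  stopifnot(
    n_nodes >= 2L, n_stimuli >= 1L, n_inhibitors >= 0L,
    k_timepoints >= 2L, noise_sd >= 0, edge_density >= 0, edge_density <= 1,
    steps_max >= 1L
  )
  if (n_stimuli >= n_nodes) {
    stop("at least one non-stimulus node is required", call. = FALSE)
  }
  if (is.null(n_readouts)) {
    n_readouts <- max(1L, n_nodes - n_stimuli - n_inhibitors - 1L)
  }
  stopifnot(n_readouts >= 1L)
  if (n_stimuli + n_inhibitors + n_readouts > n_nodes) {
    stop("role counts exceed n_nodes", call. = FALSE)
  }
  bad <- setdiff(defects, c("missing_t0", "duplicate_timepoint", "inhibitor_dynamic"))
  if (length(bad) > 0L) stop("unknown defect(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(
    n_nodes = as.integer(n_nodes), edge_density = edge_density,
    n_stimuli = as.integer(n_stimuli), n_inhibitors = as.integer(n_inhibitors),
    n_readouts = as.integer(n_readouts),
    n_perturbations = as.integer(n_perturbations),
    k_timepoints = as.integer(k_timepoints), noise_sd = noise_sd,
    defects = defects, steps_max = as.integer(steps_max),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a random prior knowledge network
#'
#' Builds a seeded random signed digraph in which stimuli have no parents,
#' every non-stimulus node has at least one parent among earlier nodes (so
#' every readout is reachable from some stimulus), extra forward and a few
#' feedback edges are added at `edge_density`, and roles are assigned
#' according to the configured counts (inhibitors double as readouts).
#'
#' @param config A [sim_config()].
#' @return A [pkn()].
#' @export
generate_pkn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_nodes
  nodes <- sprintf("v%02d", seq_len(n))
  stim <- nodes[seq_len(config$n_stimuli)]
  others <- setdiff(nodes, stim)
  src <- character(0)
  sgn <- integer(0)
  tgt <- character(0)
  rand_sign <- function(k) sample(c(1L, -1L), k, replace = TRUE, prob = c(0.75, 0.25))
  for (i in (config$n_stimuli + 1L):n) {
    parents <- sample(seq_len(i - 1L), min(i - 1L, sample(1:2, 1L)))
    src <- c(src, nodes[parents])
    tgt <- c(tgt, rep(nodes[i], length(parents)))
    sgn <- c(sgn, rand_sign(length(parents)))
    # extra forward edges
    pool <- setdiff(seq_len(i - 1L), parents)
    extra <- pool[runif(length(pool)) < config$edge_density]
    if (length(extra) > 0L) {
      src <- c(src, nodes[extra])
      tgt <- c(tgt, rep(nodes[i], length(extra)))
      sgn <- c(sgn, rand_sign(length(extra)))
    }
  }
  # sparse feedback among non-stimulus nodes
  for (i in (config$n_stimuli + 1L):(n - 1L)) {
    if (runif(1) < config$edge_density / 2) {
      j <- sample((i + 1L):n, 1L)
      if (!nodes[i] %in% stim) {
        src <- c(src, nodes[j])
        tgt <- c(tgt, nodes[i])
        sgn <- c(sgn, rand_sign(1L))
      }
    }
  }
  edges <- distinct(tibble(source = src, sign = sgn, target = tgt))
  # stimuli can end up isolated in sparse draws; declare the universe explicitly
  inhib <- sample(others, config$n_inhibitors)
  rest <- setdiff(others, inhib)
  reads <- sample(rest, config$n_readouts)
  roles <- c(
    setNames(rep("stimulus", length(stim)), stim),
    setNames(rep("inhibitor_and_readout", length(inhib)), inhib),
    setNames(rep("readout", length(reads)), reads)
  )
  pkn(edges, roles = roles, nodes = nodes)
}

#' Draw a ground-truth Boolean network from a PKN's clause space
#'
#' For every node with regulators, samples uniformly a non-empty disjunction
#' of clauses from [clause_space()] under the given caps; unregulated nodes
#' keep the identity function. The result always lies in the learner's
#' candidate space for the same caps.
#'
#' @param x A `pkn`.
#' @param max_clause_size,max_clauses_per_node Caps as in [learn_config()].
#' @param seed Seed.
#' @return A `boolean_network`.
#' @export
sample_true_bn <- function(x, max_clause_size = 2L, max_clauses_per_node = 3L,
                           seed = 1L) {
  stopifnot(inherits(x, "pkn"))
  set.seed(seed)
  cs <- clause_space(x, max_clause_size)
  if (nrow(cs) == 0L) stop("degenerate clause space", call. = FALSE)
  fns <- list()
  for (nd in unique(cs$target)) {
    tbl <- cs[cs$target == nd, ]
    opts <- node_options(tbl$clause_id, max_clauses_per_node)
    opts <- opts[lengths(opts) > 0L]
    pick <- opts[[sample.int(length(opts), 1L)]]
    fns[[nd]] <- tbl$literals[match(pick, tbl$clause_id)]
  }
  boolean_network(x$nodes, fns)
}

#' Default perturbation panel
#'
#' A deterministic panel in the style of perturbation screens: each stimulus
#' toggled on alone, then single stimuli combined with each applied
#' inhibitor, then all stimuli together, truncated or recycled with pairwise
#' stimulus combinations to reach `n`.
#'
#' @param x A `pkn`.
#' @param n Number of perturbations.
#' @return Tibble with columns `perturbation`, `node`, `value`.
#' @export
default_perturbations <- function(x, n) {
  stim <- pkn_nodes(x, "stimulus")
  inhib <- pkn_nodes(x, "inhibitor")
  combos <- list()
  for (s in stim) combos[[length(combos) + 1L]] <- list(on = s, inh = character(0))
  for (i in inhib) {
    for (s in stim) combos[[length(combos) + 1L]] <- list(on = s, inh = i)
  }
  combos[[length(combos) + 1L]] <- list(on = stim, inh = character(0))
  if (length(stim) >= 2L) {
    prs <- combn(stim, 2L, simplify = FALSE)
    for (pr in prs) combos[[length(combos) + 1L]] <- list(on = pr, inh = character(0))
  }
  if (n > length(combos)) {
    stop("cannot build ", n, " distinct perturbations from this panel", call. = FALSE)
  }
  combos <- combos[seq_len(n)]
  rows <- imap(combos, function(cb, i) {
    tibble(
      perturbation = sprintf("p%02d", i),
      node = c(stim, inhib),
      value = as.integer(c(stim %in% cb$on, inhib %in% cb$inh))
    )
  })
  bind_rows(rows)
}

#' Simulate a noisy perturbation screen from a Boolean network
#'
#' For each perturbation, runs a seeded random walk in the any-subset
#' transition system from a clamp-consistent initial state, records
#' `k_timepoints` states, and emits continuous values for the observed nodes
#' by band-coding (0 in U(0.05, 0.35), 1 in U(0.65, 0.95)) plus Gaussian
#' noise, clipped to \[0,1\]. Binarization at 0.5 therefore recovers the
#' hidden states exactly when `noise_sd = 0`. Configured QC defects are
#' injected last. The hidden binary traces are attached as `attr(x, "truth")`
#' for oracle tests, the role map as `attr(x, "roles")`, and control readings
#' as `attr(x, "control")`.
#'
#' @param bn The ground-truth `boolean_network`.
#' @param x The `pkn` the network was drawn from (supplies roles).
#' @param config A [sim_config()].
#' @param perturbations Optional perturbation table (default
#'   [default_perturbations()]).
#' @return A raw `pert_ts`.
#' @export
simulate_dataset <- function(bn, x, config, perturbations = NULL) {
  stopifnot(inherits(bn, "boolean_network"), inherits(x, "pkn"),
    inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  roles <- x$roles
  if (is.null(perturbations)) {
    perturbations <- default_perturbations(x, config$n_perturbations)
  }
  perturbations <- as_tibble(perturbations)
  cp <- compile_bn(bn)
  nodes <- bn$nodes
  observed <- pkn_nodes(x, "readout")
  k <- config$k_timepoints
  timepoints <- if (k == 7L) c(0, 5, 15, 30, 60, 120, 240) else seq(0, by = 30, length.out = k)

  emit <- function(b) {
    v <- ifelse(b == 1L, runif(length(b), 0.65, 0.95), runif(length(b), 0.05, 0.35))
    pmin(pmax(v + rnorm(length(b), 0, config$noise_sd), 0), 1)
  }

  meas <- list()
  truth <- list()
  for (p in unique(perturbations$perturbation)) {
    st <- perturbations[perturbations$perturbation == p, ]
    cl <- clamping(setNames(st$value, st$node), roles)
    pcl <- pack_clamp(cl, nodes)
    freebits <- cp$bits[bitwAnd(pcl$mask, cp$bits) == 0L]
    s <- bitwOr(pcl$value, as.integer(sum(freebits[runif(length(freebits)) < 0.5])))
    tr <- matrix(0L, nrow = k, ncol = length(nodes), dimnames = list(NULL, nodes))
    tr[1L, ] <- unpack_state(s, nodes)
    for (j in 2L:k) {
      for (step in seq_len(sample.int(config$steps_max, 1L))) {
        succ <- cp_successors(cp, s, pcl$mask)
        if (length(succ) == 0L) break
        s <- succ[sample.int(length(succ), 1L)]
      }
      tr[j, ] <- unpack_state(s, nodes)
    }
    truth[[p]] <- tr
    meas[[p]] <- tibble(
      perturbation = p,
      time = rep(timepoints, each = length(observed)),
      node = rep(observed, k),
      value = emit(as.vector(t(tr[, observed, drop = FALSE])))
    )
  }
  measurements <- bind_rows(meas)
  control <- setNames(runif(length(observed), 0.05, 0.35), observed)

  if ("missing_t0" %in% config$defects) {
    p1 <- unique(perturbations$perturbation)[1]
    nd <- observed[1]
    sel <- measurements$perturbation == p1 & measurements$time == timepoints[1] &
      measurements$node == nd
    measurements$value[sel] <- NA_real_
  }
  if ("duplicate_timepoint" %in% config$defects) {
    p1 <- unique(perturbations$perturbation)[1]
    tmid <- timepoints[ceiling(k / 2)]
    dup <- measurements[measurements$perturbation == p1 & measurements$time == tmid, ]
    dup$value <- pmin(pmax(dup$value + rnorm(nrow(dup), 0, 0.05), 0), 1)
    measurements <- bind_rows(measurements, dup)
  }
  pert_out <- perturbations
  if ("inhibitor_dynamic" %in% config$defects) {
    inhib <- intersect(pkn_nodes(x, "inhibitor"), observed)
    if (length(inhib) == 0L) {
      stop("inhibitor_dynamic defect needs an inhibitor that is also a readout",
        call. = FALSE
      )
    }
    nd <- inhib[1]
    stim <- pkn_nodes(x, "stimulus")
    pid <- sprintf("p%02d", length(unique(perturbations$perturbation)) + 1L)
    pert_out <- bind_rows(pert_out, tibble(
      perturbation = pid,
      node = c(stim, pkn_nodes(x, "inhibitor")),
      value = as.integer(c(stim == stim[1], pkn_nodes(x, "inhibitor") == nd))
    ))
    vals <- rep(c(0.9, 0.1), length.out = k) # oscillating inhibited readout
    rows <- tibble(
      perturbation = pid,
      time = rep(timepoints, each = length(observed)),
      node = rep(observed, k),
      value = as.vector(vapply(seq_len(k), function(j) {
        v <- emit(rep(0L, length(observed)))
        v[match(nd, observed)] <- vals[j]
        v
      }, numeric(length(observed))))
    )
    measurements <- bind_rows(measurements, rows)
  }

  out <- pert_ts(measurements, pert_out)
  attr(out, "roles") <- roles
  attr(out, "truth") <- truth
  attr(out, "control") <- control
  out
}
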