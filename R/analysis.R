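#' Families of Boolean networks
#'
#' A labelled collection of Boolean networks over one node universe —
#' typically the co-optimal networks learned for one biological context (cell
#' line), optionally restricted to the certified true positives.
#'
#' @param networks List of `boolean_network` objects (non-empty, identical
#'   node sets).
#' @param label Family label (e.g. the cell line).
#' @return An object of class `bn_family`.
#' @export
bn_family <- function(networks, label = "family") {
  if (inherits(networks, "bn_learn")) networks <- map(networks$results, "bn")
  stopifnot(length(networks) >= 1L)
  if (!all(map_lgl(networks, inherits, "boolean_network"))) {
    stop("all family members must be boolean_network objects", call. = FALSE)
  }
  uni <- networks[[1]]$nodes
  if (!all(map_lgl(networks, ~ identical(.x$nodes, uni)))) {
    stop("family members must share one node universe", call. = FALSE)
  }
  structure(list(networks = networks, label = label, nodes = uni),
    class = "bn_family"
  )
}

#' @export
print.bn_family <- function(x, ...) {
  cat(sprintf(
    "<bn_family '%s'> %d network(s) over %d nodes\n",
    x$label, length(x$networks), length(x$nodes)
  ))
  invisible(x)
}

#' Hyper-edge frequencies within a family
#'
#' The frequency of a hyper-edge (one clause of one node's function) is the
#' fraction of family members containing it.
#'
#' @param family A [bn_family()].
#' @return Tibble with columns `target`, `clause`, `hyperedge`, `frequency`
#'   (in (0, 1\]), sorted by decreasing frequency.
#' @export
hyperedge_frequencies <- function(family) {
  stopifnot(inherits(family, "bn_family"))
  all_he <- bind_rows(map(family$networks, bn_hyperedges))
  all_he %>%
    count(target, clause, hyperedge, name = "n_members") %>%
    mutate(frequency = n_members / length(family$networks)) %>%
    select(-n_members) %>%
    arrange(dplyr::desc(frequency), hyperedge)
}

#' Aggregate a family into a consensus network
#'
#' Keeps the hyper-edges whose family frequency is strictly greater than the
#' threshold (default 0.3).
#'
#' @param family A [bn_family()].
#' @param threshold Frequency cutoff; strict inequality, so a hyper-edge at
#'   exactly the threshold is dropped and `threshold = 0` keeps the union.
#' @return An object of class `bn_aggregate`: the kept hyper-edge tibble plus
#'   the threshold and node universe.
#' @export
aggregate_family <- function(family, threshold = 0.3) {
  stopifnot(inherits(family, "bn_family"), threshold >= 0, threshold < 1)
  he <- hyperedge_frequencies(family) %>% filter(frequency > threshold)
  structure(
    list(
      hyperedges = he, threshold = threshold, nodes = family$nodes,
      label = family$label
    ),
    class = "bn_aggregate"
  )
}

#' @export
print.bn_aggregate <- function(x, ...) {
  cat(sprintf(
    "<bn_aggregate '%s'> %d hyper-edge(s) at frequency > %.2f\n",
    x$label, nrow(x$hyperedges), x$threshold
  ))
  invisible(x)
}

#' @export
tidy.bn_aggregate <- function(x, ...) x$hyperedges

#' Jaccard similarity of two hyper-edge sets
#'
#' `|a ∩ b| / (|a| + |b| - |a ∩ b|)`; two empty sets are defined as
#' identical (similarity 1).
#'
#' @param a,b Character vectors of hyper-edges (or objects with a hyper-edge
#'   set: `boolean_network`, `bn_aggregate`).
#' @return A value in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- as_hyperedge_set(a)
  b <- as_hyperedge_set(b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  i <- length(intersect(a, b))
  i / (length(a) + length(b) - i)
}

as_hyperedge_set <- function(x) {
  if (inherits(x, "boolean_network")) return(hyperedge_set(x))
  if (inherits(x, "bn_aggregate")) return(x$hyperedges$hyperedge)
  unique(as.character(x))
}

#' Average similarity of a family to a gold-standard network
#'
#' The mean Jaccard similarity between the gold standard's hyper-edge set and
#' each family member's. Used within a family (gold = the family's own
#' aggregate) to measure its homogeneity, and across families (gold = another
#' family's aggregate) to compare contexts; the cross comparison is not
#' symmetric, so report both orientations.
#'
#' @param gold Hyper-edge set (or `boolean_network` / `bn_aggregate`).
#' @param family A [bn_family()].
#' @return A value in \[0, 1\].
#' @export
family_similarity <- function(gold, family) {
  stopifnot(inherits(family, "bn_family"))
  g <- as_hyperedge_set(gold)
  mean(map_dbl(family$networks, ~ jaccard(g, .x)))
}

#' Pairwise similarity matrix of several families
#'
#' @param families List of [bn_family()] objects.
#' @param threshold Aggregation threshold for the gold standards.
#' @return Tibble in long form: `gold`, `family`, `similarity`; the diagonal
#'   entries are each family's internal homogeneity.
#' @export
similarity_matrix <- function(families, threshold = 0.3) {
  labs <- map_chr(families, "label")
  golds <- map(families, aggregate_family, threshold = threshold)
  rows <- list()
  for (i in seq_along(families)) {
    for (j in seq_along(families)) {
      rows[[length(rows) + 1L]] <- tibble(
        gold = labs[i], family = labs[j],
        similarity = family_similarity(golds[[i]], families[[j]])
      )
    }
  }
  bind_rows(rows)
}

#' Ratio of discretization floor to model error
#'
#' `discrete / model`, at most 1 by construction; equals 1 exactly when the
#' model reproduces the binarized data without penalty.
#'
#' @param discrete Discrete (floor) RMSE.
#' @param model Model RMSE.
#' @return A value in \[0, 1\].
#' @export
rmse_ratio <- function(discrete, model) {
  stopifnot(length(discrete) == length(model))
  out <- numeric(length(model))
  for (i in seq_along(model)) {
    if (model[i] == 0) {
      if (discrete[i] == 0) {
        out[i] <- 1
      } else {
        stop("model RMSE of 0 with a positive discrete RMSE is impossible", call. = FALSE)
      }
    } else {
      out[i] <- discrete[i] / model[i]
    }
  }
  out
}

#' Random-data specificity check
#'
#' Replaces every readout value at every time point with an independent
#' uniform \[0,1\] draw (perturbations unchanged), then computes the best
#' model RMSE attainable by any network of the family on the resampled data —
#' trace search with the network fixed — together with the sample's own
#' discretization floor. Structured data fitted exactly gives ratio 1;
#' random data should give ratios below 1, demonstrating the family is
#' specific to the data it was learned from.
#'
#' @param family A [bn_family()].
#' @param data The normalized `pert_ts` the family explains.
#' @param roles Named role vector or `pkn`.
#' @param n_samples Number of resamples (default 100).
#' @param seed Seed for the uniform draws.
#' @param threshold Binarization threshold.
#' @return Tibble with one row per sample: `sample`, `discrete_rmse`,
#'   `model_rmse`, `ratio`.
#' @export
random_validation <- function(family, data, roles, n_samples = 100L, seed = 1L,
                              threshold = 0.5) {
  stopifnot(inherits(family, "bn_family"))
  validate_pert_ts(data, allow_missing = FALSE)
  if (inherits(roles, "pkn")) roles <- roles$roles
  set.seed(seed)
  engine <- family_fit_engine(family, data, roles, threshold)
  out <- list()
  for (s in seq_len(n_samples)) {
    smp <- data
    smp$measurements$value <- runif(nrow(smp$measurements))
    fit <- engine(smp)
    out[[s]] <- tibble(
      sample = s, discrete_rmse = fit$discrete_rmse, model_rmse = fit$model_rmse,
      ratio = rmse_ratio(fit$discrete_rmse, fit$model_rmse)
    )
  }
  if (length(out) == 0L) {
    return(tibble(
      sample = integer(), discrete_rmse = numeric(),
      model_rmse = numeric(), ratio = numeric()
    ))
  }
  bind_rows(out)
}

# Precompute, per (network, perturbation), the support-consistency adjacency
# over candidate states (it depends only on the network and the clamping), and
# return a closure that fits any dataset with the same perturbation design by
# min-plus dynamic programming over time points.
family_fit_engine <- function(family, data, roles, threshold = 0.5) {
  stopifnot(inherits(family, "bn_family"))
  if (inherits(roles, "pkn")) roles <- roles$roles
  tp0 <- trace_problem(family$nodes, data, roles, threshold)
  adj <- lapply(family$networks, function(bn) {
    cp <- compile_bn(bn)
    lapply(tp0$perts, function(pp) {
      ns <- length(pp$states)
      M <- matrix(Inf, ns, ns)
      for (s in seq_len(ns)) {
        ok <- sc_query_many(cp, pp$states[s], pp$clampmask, pp$clampval, pp$states)
        M[s, ok] <- 0
      }
      M
    })
  })
  function(new_data) {
    tp <- trace_problem(family$nodes, new_data, roles, threshold)
    best <- Inf
    best_i <- NA_integer_
    for (i in seq_along(adj)) {
      tot <- 0
      for (pi in seq_along(tp$perts)) {
        ex <- tp$perts[[pi]]$excess
        M <- adj[[i]][[pi]]
        dp <- ex[, 1L]
        for (j in seq(2L, tp$k)) {
          dp <- ex[, j] + suppressWarnings(apply(M + dp, 2L, min))
        }
        tot <- tot + suppressWarnings(min(dp))
        if (tot >= best) break
      }
      if (tot < best) {
        best <- tot
        best_i <- i
      }
    }
    list(
      model_rmse = sqrt((tp$floor_sq + best) / tp$ncells),
      discrete_rmse = sqrt(tp$floor_sq / tp$ncells),
      best_network = best_i
    )
  }
}

#' Best attainable fit of a fixed family on a dataset
#'
#' Minimum model RMSE over the family's networks with the networks fixed
#' (only the binary traces are optimized, still subject to clamping and
#' support consistency), plus the dataset's discretization floor.
#'
#' @inheritParams random_validation
#' @param data A normalized `pert_ts`.
#' @return List with `model_rmse`, `discrete_rmse`, `best_network` (index).
#' @export
family_best_fit <- function(family, data, roles, threshold = 0.5) {
  family_fit_engine(family, data, roles, threshold)(data)
}

#' Downstream node set of a network
#'
#' All nodes reachable from `root` by directed traversal of the hyper-edge
#' structure (each clause regulator points at its target), excluding the root
#' itself.
#'
#' @param x A `boolean_network`, `bn_aggregate`, or `pkn`.
#' @param root Node name.
#' @return Character vector of downstream nodes.
#' @export
downstream_set <- function(x, root) {
  g <- as_edge_graph(x)
  if (!root %in% igraph::V(g)$name) stop("unknown root node: ", root, call. = FALSE)
  down <- igraph::subcomponent(g, root, mode = "out")$name
  setdiff(down, root)
}

as_edge_graph <- function(x) {
  ed <- if (inherits(x, "pkn")) {
    x$edges %>% select(from = source, to = target)
  } else {
    he <- if (inherits(x, "bn_aggregate")) x$hyperedges else bn_hyperedges(x)
    if (nrow(he) == 0L) {
      tibble(from = character(), to = character())
    } else {
      bind_rows(lapply(seq_len(nrow(he)), function(i) {
        tibble(from = names(parse_clause(he$clause[i])), to = he$target[i])
      }))
    }
  }
  nodes <- if (inherits(x, "pkn")) x$nodes else x$nodes
  igraph::graph_from_data_frame(distinct(ed), directed = TRUE,
    vertices = tibble(name = nodes))
}

#' True and false positive rates of an inferred node set
#'
#' `TPR = |standard ∩ inferred| / |standard|` and
#' `FPR = |inferred \ standard| / |universe \ standard|`.
#'
#' @param standard Gold-standard node set (non-empty).
#' @param inferred Inferred node set.
#' @param universe Full node universe (must strictly contain `standard`).
#' @return Tibble with columns `tpr`, `fpr`.
#' @export
tpr_fpr <- function(standard, inferred, universe) {
  standard <- unique(standard)
  inferred <- unique(inferred)
  universe <- unique(universe)
  if (!all(standard %in% universe) || !all(inferred %in% universe)) {
    stop("standard and inferred sets must be subsets of the universe", call. = FALSE)
  }
  if (length(standard) == 0L) stop("TPR undefined: empty standard set", call. = FALSE)
  neg <- setdiff(universe, standard)
  if (length(neg) == 0L) stop("FPR undefined: universe equals the standard set", call. = FALSE)
  tibble(
    tpr = length(intersect(standard, inferred)) / length(standard),
    fpr = length(setdiff(inferred, standard)) / length(neg)
  )
}

#' Area under the ROC point cloud of a network family
#'
#' One (FPR, TPR) point per network; points are sorted by FPR (ties resolved
#' by keeping the best TPR at each FPR — the upper envelope), anchored at
#' (0,0) and (1,1), and integrated by the trapezoidal rule.
#'
#' @param points Data frame with columns `fpr`, `tpr` in \[0,1\].
#' @return AUROC value in \[0, 1\].
#' @export
family_auroc <- function(points) {
  pts <- as_tibble(points) %>%
    select(fpr, tpr) %>%
    distinct() %>%
    group_by(fpr) %>%
    summarise(tpr = max(tpr), .groups = "drop") %>%
    arrange(fpr)
  x <- c(0, pts$fpr, 1)
  y <- c(0, pts$tpr, 1)
  keep <- !duplicated(x) | c(TRUE, diff(y) != 0)
  x <- x[keep]
  y <- y[keep]
  # envelope may re-introduce duplicate anchors at 0/1; collapse to max tpr
  agg <- tapply(y, x, max)
  x <- as.numeric(names(agg))
  y <- as.numeric(agg)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Betweenness-style centrality on the hyper-edge graph
#'
#' Fraction of shortest directed source–target paths passing through the
#' node, averaged over the ordered pairs (s, t) that avoid the node and are
#' actually connected. A node in the middle of the only path of a graph
#' scores 1; a leaf scores 0.
#'
#' @param x A `boolean_network`, `bn_aggregate`, or `pkn`.
#' @param node Node name.
#' @return A value in \[0, 1\].
#' @export
node_centrality <- function(x, node) {
  g <- as_edge_graph(x)
  vs <- igraph::V(g)$name
  if (!node %in% vs) stop("unknown node: ", node, call. = FALSE)
  others <- setdiff(vs, node)
  d <- igraph::distances(g, v = others, to = others, mode = "out")
  num <- 0
  denom <- 0
  for (s in others) {
    for (t in others) {
      if (s == t || !is.finite(d[s, t])) next
      denom <- denom + 1
      paths <- igraph::all_shortest_paths(g, from = s, to = t, mode = "out")$res
      through <- sum(map_lgl(paths, ~ node %in% .x$name))
      num <- num + through / length(paths)
    }
  }
  if (denom == 0) return(0)
  num / denom
}
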