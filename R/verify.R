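# Exact certification of learned networks: a network is a true positive (TP)
# when, for every perturbation, the corrected binarized observation sequence
# can be threaded through the state graph — the explicit-state equivalent of
# the nested CTL reachability EF(s1 & EF(s2 & ...)). Unobserved components are
# existentially free at every anchor.

# Ancestors of the observed nodes in the regulatory graph (cone of influence);
# nodes outside it can never change an observed value, so they are dropped
# before state-space construction, which preserves verdicts.
cone_of_influence <- function(bn, observed) {
  preds <- imap(bn$functions, function(cls, nd) unique(unlist(lapply(cls, names))))
  cone <- intersect(bn$nodes, observed)
  frontier <- cone
  while (length(frontier) > 0L) {
    new <- setdiff(unique(unlist(preds[frontier])), cone)
    cone <- c(cone, new)
    frontier <- new
  }
  bn$nodes[bn$nodes %in% cone]
}

restrict_bn <- function(bn, keep) {
  boolean_network(keep, bn$functions[intersect(names(bn$functions), keep)])
}

# Multi-source BFS that records parent pointers for witness reconstruction.
reach_set_parents <- function(cp, sources, clampmask, budget) {
  size <- cp$full + 1L
  parent <- rep(NA_integer_, size)
  parent[sources + 1L] <- -1L # source marker
  frontier <- unique(sources)
  explored <- length(frontier)
  repeat {
    nxt <- integer(0)
    for (x in frontier) {
      succ <- cp_successors(cp, x, clampmask)
      new <- succ[is.na(parent[succ + 1L])]
      if (length(new) == 0L) next
      parent[new + 1L] <- x
      nxt <- c(nxt, new)
      explored <- explored + length(new)
      if (explored > budget) {
        return(list(parent = parent, explored = explored, budget_exceeded = TRUE))
      }
    }
    if (length(nxt) == 0L) break
    frontier <- nxt
  }
  list(parent = parent, explored = explored, budget_exceeded = FALSE)
}

#' Certify a Boolean network against corrected binarized trajectories
#'
#' For each perturbation, computes the set of full states matching the first
#' observation (unobserved components free, clamping enforced), then
#' repeatedly takes all states reachable from that frontier and intersects
#' with the next observation; the trajectory passes when the final frontier is
#' non-empty. The network is `TP` when every perturbation passes, `FP` when
#' some observation transition is exactly unreachable, and `undecided` only
#' when the exploration budget was exhausted.
#'
#' Verification runs on the cone of influence of the observed nodes (their
#' regulatory ancestors), which preserves verdicts while shrinking the state
#' space.
#'
#' @param bn A `boolean_network`.
#' @param corrected A binarized `pert_ts` of corrected observations (e.g. the
#'   `corrected` element of a `bn_fit`).
#' @param roles Named role vector (or `pkn`) used to derive each
#'   perturbation's clamping; defaults to the `roles` attribute of
#'   `corrected`.
#' @param budget Maximum states explored per perturbation (explored states,
#'   not wall-clock, for determinism).
#' @param witness Keep a witness path per passing perturbation (a matrix of
#'   full cone states threading all observations), used to replay the
#'   certificate.
#' @return An object of class `bn_verdict` with `status` (`"TP"`, `"FP"`,
#'   `"undecided"`), `detail` (per-perturbation tibble: `pass`,
#'   `fail_transition` — index of the first unreachable observation step —
#'   and `states_explored`), and optionally `witnesses`.
#' @export
verify <- function(bn, corrected, roles = attr(corrected, "roles"),
                   budget = 2^20, witness = FALSE) {
  stopifnot(inherits(bn, "boolean_network"), inherits(corrected, "pert_ts"))
  if (!corrected$binarized) stop("`corrected` must be binarized", call. = FALSE)
  if (inherits(roles, "pkn")) roles <- roles$roles
  if (is.null(roles)) stop("roles are required to derive clampings", call. = FALSE)
  observed <- pts_observed(corrected)
  unknown <- setdiff(observed, bn$nodes)
  if (length(unknown) > 0L) {
    stop("observation references unknown node(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  timepoints <- pts_timepoints(corrected)
  k <- length(timepoints)
  cone <- cone_of_influence(bn, observed)
  sub <- restrict_bn(bn, cone)
  if (length(cone) > 20L) {
    stop("cone of influence exceeds 20 nodes; explicit-state checking refused",
      call. = FALSE
    )
  }
  cp <- compile_bn(sub)
  bits <- cp$bits
  obs_bits <- bits[match(observed, cone)]

  detail <- list()
  witnesses <- list()
  overall_budget_hit <- FALSE
  for (p in pts_perturbations(corrected)) {
    cl <- clamping(pts_settings(corrected, p), roles)
    cl <- cl[names(cl) %in% cone]
    pcl <- pack_clamp(cl, cone)
    mm <- corrected$measurements[corrected$measurements$perturbation == p, ]
    obsvals <- vapply(seq_len(k), function(j) {
      v <- mm$value[match(paste(timepoints[j], observed), paste(mm$time, mm$node))]
      as.integer(sum(obs_bits[v == 1]))
    }, integer(1))
    obsmask <- as.integer(sum(obs_bits))
    anchor_mask <- bitwOr(obsmask, pcl$mask)
    free <- bits[bitwAnd(anchor_mask, bits) == 0L]

    anchor_states <- function(j) {
      if (bitwAnd(obsvals[j], pcl$mask) != bitwAnd(pcl$value, obsmask)) {
        return(integer(0)) # observation contradicts the clamping
      }
      base <- bitwOr(obsvals[j], pcl$value)
      states <- base
      for (b in free) states <- c(states, states + b)
      states
    }

    frontier <- anchor_states(1L)
    explored <- length(frontier)
    pass <- TRUE
    fail_at <- NA_integer_
    budget_hit <- FALSE
    parents <- vector("list", max(k - 1L, 0L))
    frontiers <- list(frontier)
    if (length(frontier) == 0L) {
      pass <- FALSE
      fail_at <- 0L
    } else if (k > 1L) {
      for (j in seq_len(k - 1L)) {
        rs <- reach_set_parents(cp, frontier, pcl$mask, budget)
        explored <- explored + rs$explored
        if (rs$budget_exceeded) {
          budget_hit <- TRUE
          overall_budget_hit <- TRUE
          pass <- NA
          fail_at <- j
          break
        }
        nxt <- anchor_states(j + 1L)
        nxt <- nxt[!is.na(rs$parent[nxt + 1L])]
        if (length(nxt) == 0L) {
          pass <- FALSE
          fail_at <- j
          break
        }
        parents[[j]] <- rs$parent
        frontier <- nxt
        frontiers[[j + 1L]] <- nxt
      }
    }
    if (isTRUE(pass) && witness) {
      witnesses[[p]] <- build_witness(parents, frontiers, k, cone)
    }
    detail[[p]] <- tibble(
      perturbation = p, pass = pass, fail_transition = fail_at,
      states_explored = explored, budget_hit = budget_hit
    )
  }
  detail <- bind_rows(detail)
  status <- if (any(is.na(detail$pass))) {
    "undecided"
  } else if (all(detail$pass)) "TP" else "FP"
  structure(list(
    status = status, detail = detail, cone = cone,
    states_explored = sum(detail$states_explored),
    budget_hit = overall_budget_hit,
    witnesses = if (witness) witnesses else NULL
  ), class = "bn_verdict")
}

# Reconstruct one full path through all anchors from the BFS parent vectors.
build_witness <- function(parents, frontiers, k, cone) {
  end <- frontiers[[k]][1]
  segs <- list()
  cur <- end
  for (j in rev(seq_len(k - 1L))) {
    seg <- cur
    par <- parents[[j]]
    while (par[cur + 1L] != -1L) {
      cur <- par[cur + 1L]
      seg <- c(cur, seg)
    }
    segs[[j]] <- seg
  }
  path <- unlist(lapply(seq_along(segs), function(j) {
    if (j == 1L) segs[[j]] else segs[[j]][-1L]
  }))
  if (k == 1L) path <- end
  anchors <- integer(k)
  anchors[1] <- 1L
  if (k > 1L) {
    pos <- 1L
    for (j in seq_len(k - 1L)) {
      pos <- pos + length(segs[[j]]) - 1L
      anchors[j + 1L] <- pos
    }
  }
  mat <- t(vapply(path, unpack_state, integer(length(cone)), nodes = cone))
  list(path = mat, anchors = anchors)
}

#' @export
print.bn_verdict <- function(x, ...) {
  cat(sprintf(
    "<bn_verdict> %s (%d perturbation(s), %d states explored)\n",
    x$status, nrow(x$detail), x$states_explored
  ))
  invisible(x)
}

#' @export
tidy.bn_verdict <- function(x, ...) x$detail

#' Verify a family of learned networks under a budget
#'
#' Runs [verify()] over the results of [learn()] in enumeration order until a
#' total exploration budget is exhausted; remaining networks are `undecided`.
#'
#' @param fit A `bn_learn` object.
#' @param roles Named role vector or `pkn` for clampings.
#' @param budget_per_bn Exploration budget per network (states).
#' @param total_budget Total exploration budget across networks (states).
#' @param witness Passed to [verify()].
#' @return A tibble with one row per network (`model`, `status`,
#'   `states_explored`) plus the verdict objects in the `verdict` list
#'   column.
#' @export
triage <- function(fit, roles, budget_per_bn = 2^20, total_budget = Inf,
                   witness = FALSE) {
  stopifnot(inherits(fit, "bn_learn"))
  rows <- list()
  spent <- 0
  for (i in seq_along(fit$results)) {
    if (spent >= total_budget) {
      rows[[i]] <- tibble(
        model = i, status = "undecided", states_explored = 0,
        verdict = list(NULL)
      )
      next
    }
    v <- verify(fit$results[[i]]$bn, fit$results[[i]]$corrected,
      roles = roles, budget = budget_per_bn, witness = witness
    )
    spent <- spent + v$states_explored
    rows[[i]] <- tibble(
      model = i, status = v$status, states_explored = v$states_explored,
      verdict = list(v)
    )
  }
  bind_rows(rows)
}
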