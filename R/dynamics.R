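# Explicit-state semantics of Boolean networks under the "any number of nodes
# may update at once" schedule, plus the meta-state over-approximation of
# reachability (support consistency). States are packed integers (utils-bits.R);
# everything here is deliberately allocation-light because the learner and the
# model checker sit in tight loops on top of it.

# ---- compilation -----------------------------------------------------------

# Compile a boolean_network into mask form:
#   fns[[i]]$clauses: list of (pos, neg) masks; identity flag; regmask.
# `cache` memoizes meta-closures keyed by (state, clampmask, clampval).
compile_bn <- function(bn) {
  stopifnot(inherits(bn, "boolean_network"))
  n <- length(bn$nodes)
  bits <- bit_masks(n)
  fns <- vector("list", n)
  for (i in seq_len(n)) {
    cls <- bn$functions[[i]]
    if (length(cls) == 0L) {
      fns[[i]] <- list(identity = TRUE, pos = integer(0), neg = integer(0), regmask = bits[i])
    } else {
      pos <- vapply(cls, function(cl) {
        idx <- match(names(cl), bn$nodes)
        as.integer(sum(bits[idx[cl > 0L]]))
      }, integer(1))
      neg <- vapply(cls, function(cl) {
        idx <- match(names(cl), bn$nodes)
        as.integer(sum(bits[idx[cl < 0L]]))
      }, integer(1))
      fns[[i]] <- list(
        identity = FALSE, pos = pos, neg = neg,
        regmask = Reduce(bitwOr, c(pos, neg), 0L)
      )
    }
  }
  list(nodes = bn$nodes, n = n, bits = bits, full = full_mask(n), fns = fns)
}

pack_clamp <- function(clamp, nodes) {
  p <- pack_partial(clamp, nodes)
  list(mask = p$mask, value = p$value)
}

# f(x) for a packed state, all nodes at once.
cp_image <- function(cp, x) {
  fx <- 0L
  for (i in seq_len(cp$n)) {
    f <- cp$fns[[i]]
    if (f$identity) {
      if (bitwAnd(x, cp$bits[i]) != 0L) fx <- bitwOr(fx, cp$bits[i])
    } else if (any(bitwAnd(x, f$pos) == f$pos & bitwAnd(x, f$neg) == 0L)) {
      fx <- bitwOr(fx, cp$bits[i])
    }
  }
  fx
}

cp_successors <- function(cp, x, clampmask) {
  fx <- cp_image(cp, x)
  diff <- bitwAnd(bitwXor(x, fx), bitwXor(cp$full, clampmask))
  bitwXor(x, submasks(diff))
}

# ---- exact reachability ----------------------------------------------------

check_clamp_respected <- function(x, clampmask, clampval, what = "state") {
  if (bitwAnd(x, clampmask) != clampval) {
    stop(what, " does not respect the clamping", call. = FALSE)
  }
}

# Multi-source BFS over the any-subset transition graph. Returns the visited
# set (integer vector, includes the sources) and whether the budget was hit.
reach_set <- function(cp, sources, clampmask, budget = 2^20,
                      stop_mask = NULL, stop_val = NULL) {
  visited <- raw(cp$full + 1L)
  visited[sources + 1L] <- as.raw(1L)
  frontier <- unique(sources)
  explored <- length(frontier)
  hit <- NULL
  if (!is.null(stop_mask)) {
    m <- frontier[bitwAnd(frontier, stop_mask) == stop_val]
    if (length(m) > 0L) hit <- m[1]
  }
  while (length(frontier) > 0L && is.null(hit)) {
    nxt <- integer(0)
    for (x in frontier) {
      succ <- cp_successors(cp, x, clampmask)
      if (length(succ) == 0L) next
      new <- succ[visited[succ + 1L] == as.raw(0L)]
      if (length(new) == 0L) next
      visited[new + 1L] <- as.raw(1L)
      nxt <- c(nxt, new)
      explored <- explored + length(new)
      if (!is.null(stop_mask)) {
        m <- new[bitwAnd(new, stop_mask) == stop_val]
        if (length(m) > 0L) {
          hit <- m[1]
          break
        }
      }
      if (explored > budget) {
        return(list(
          states = which(visited == as.raw(1L)) - 1L, explored = explored,
          budget_exceeded = TRUE, hit = hit
        ))
      }
    }
    frontier <- nxt
  }
  list(
    states = which(visited == as.raw(1L)) - 1L, explored = explored,
    budget_exceeded = FALSE, hit = hit
  )
}

#' One-step successors of a Boolean network state
#'
#' Under the schedule-free semantics, a transition updates any non-empty
#' subset of non-clamped nodes simultaneously to their regulatory function
#' value. Synchronous (all nodes) and asynchronous (one node) updates are both
#' special cases. The state itself is never returned, and clamped nodes never
#' change.
#'
#' @param bn A [boolean_network()].
#' @param x Named 0/1 state vector over all nodes of `bn`.
#' @param clamp Named 0/1 vector of clamped nodes (see [clamping()]); `x` must
#'   agree with it.
#' @return A list of named 0/1 state vectors (possibly empty, at a fixpoint).
#' @export
successors <- function(bn, x, clamp = NULL) {
  cp <- compile_bn(bn)
  cl <- pack_clamp(clamp %||% integer(0), bn$nodes)
  xi <- pack_state(x, bn$nodes)
  check_clamp_respected(xi, cl$mask, cl$value)
  lapply(cp_successors(cp, xi, cl$mask), unpack_state, nodes = bn$nodes)
}

#' Exact reachability in the state graph
#'
#' Breadth-first search over the any-subset transition graph, asking whether
#' some state matching `goal` (a partial state; unmentioned nodes are free) is
#' reachable from `x` in zero or more steps.
#'
#' @inheritParams successors
#' @param goal Named 0/1 vector over a subset of nodes.
#' @param budget Maximum number of states to explore before giving up.
#' @return `TRUE`, `FALSE`, or `NA` when the budget was exhausted (reported
#'   distinctly from `FALSE`, never conflated).
#' @export
reachable <- function(bn, x, goal, clamp = NULL, budget = 2^20) {
  cp <- compile_bn(bn)
  cl <- pack_clamp(clamp %||% integer(0), bn$nodes)
  xi <- pack_state(x, bn$nodes)
  check_clamp_respected(xi, cl$mask, cl$value)
  g <- pack_partial(goal, bn$nodes)
  res <- reach_set(cp, xi, cl$mask,
    budget = budget,
    stop_mask = g$mask, stop_val = g$value
  )
  if (!is.null(res$hit)) return(TRUE)
  if (res$budget_exceeded) return(NA)
  FALSE
}

# ---- meta-states -----------------------------------------------------------

# A meta-state is represented by two masks: can0 (bit i set iff 0 is a possible
# value of node i) and can1. Every component must be non-empty.

ms_pack <- function(u, nodes) {
  if (is.null(names(u))) stop("meta-state must be named by node", call. = FALSE)
  u <- u[nodes]
  if (anyNA(u)) stop("meta-state must cover every node", call. = FALSE)
  if (!all(u %in% c("0", "1", "*"))) {
    stop('meta-state components must be "0", "1" or "*"', call. = FALSE)
  }
  bits <- bit_masks(length(nodes))
  list(
    can0 = as.integer(sum(bits[u %in% c("0", "*")])),
    can1 = as.integer(sum(bits[u %in% c("1", "*")]))
  )
}

ms_unpack <- function(can0, can1, nodes) {
  bits <- bit_masks(length(nodes))
  has0 <- bitwAnd(can0, bits) != 0L
  has1 <- bitwAnd(can1, bits) != 0L
  setNames(ifelse(has0 & has1, "*", ifelse(has1, "1", "0")), nodes)
}

# Per-node image of f over the states of meta-state (can0, can1): which values
# each f_i can take. Regulator assignments consistent with u are enumerated
# exhaustively (regulator sets are small by construction).
ms_images <- function(cp, can0, can1) {
  img0 <- 0L
  img1 <- 0L
  both <- bitwAnd(can0, can1)
  for (i in seq_len(cp$n)) {
    f <- cp$fns[[i]]
    b <- cp$bits[i]
    if (f$identity) {
      if (bitwAnd(can0, b) != 0L) img0 <- bitwOr(img0, b)
      if (bitwAnd(can1, b) != 0L) img1 <- bitwOr(img1, b)
      next
    }
    varmask <- bitwAnd(f$regmask, both)
    base <- bitwAnd(bitwAnd(can1, f$regmask), bitwXor(cp$full, varmask))
    zs <- bitwOr(base, c(0L, submasks(varmask))) # every regulator assignment in u
    val <- rep(FALSE, length(zs))
    for (ci in seq_along(f$pos)) {
      val <- val | (bitwAnd(zs, f$pos[ci]) == f$pos[ci] & bitwAnd(zs, f$neg[ci]) == 0L)
      if (all(val)) break
    }
    if (!all(val)) img0 <- bitwOr(img0, b)
    if (any(val)) img1 <- bitwOr(img1, b)
  }
  list(img0 = img0, img1 = img1)
}

#' Meta-state widening steps
#'
#' A meta-state assigns each node a non-empty subset of \{0, 1\}, written
#' `"0"`, `"1"` or `"*"` (= both). A widening step replaces one component
#' `u_i` by `u_i` united with the image of `f_i` over all states belonging to
#' `u`; only strict growth counts, and clamped components are never widened.
#' Chains of widening steps over-approximate reachability.
#'
#' @inheritParams successors
#' @param u Named character vector over all nodes with values `"0"`, `"1"`,
#'   `"*"`.
#' @return List of meta-states (same representation) reachable in one step.
#' @export
meta_successors <- function(bn, u, clamp = NULL) {
  cp <- compile_bn(bn)
  cl <- pack_clamp(clamp %||% integer(0), bn$nodes)
  mu <- ms_pack(u, bn$nodes)
  # clamped components must be singletons at the clamp value
  both <- bitwAnd(mu$can0, mu$can1)
  if (bitwAnd(both, cl$mask) != 0L ||
    bitwAnd(mu$can1, cl$mask) != cl$value) {
    stop("clamped components must be fixed at the clamp value", call. = FALSE)
  }
  imgs <- ms_images(cp, mu$can0, mu$can1)
  out <- list()
  free <- bitwXor(cp$full, cl$mask)
  for (i in seq_len(cp$n)) {
    b <- cp$bits[i]
    if (bitwAnd(free, b) == 0L) next
    n0 <- bitwOr(mu$can0, bitwAnd(imgs$img0, b))
    n1 <- bitwOr(mu$can1, bitwAnd(imgs$img1, b))
    if (n0 != mu$can0 || n1 != mu$can1) {
      out <- c(out, list(ms_unpack(n0, n1, bn$nodes)))
    }
  }
  out
}

# Meta-closure from the singleton meta-state of x: all meta-states reachable by
# zero or more widening steps. Because each component starts as a singleton
# {x_i} and widening unions in the image while keeping u_i, components only
# ever grow from {x_i} to {0,1}; a reachable meta-state is therefore encoded by
# its set W of widened components. Stores per meta-state the image masks needed
# for the support-consistency conditions.
meta_closure <- function(cp, x, clampmask, clampval) {
  notx <- bitwXor(x, cp$full)
  free <- bitwXor(cp$full, clampmask)
  seen <- new.env(parent = emptyenv())
  Ws <- integer(0)
  img0s <- integer(0)
  img1s <- integer(0)
  queue <- 0L
  seen[["0"]] <- TRUE
  while (length(queue) > 0L) {
    W <- queue[[1]]
    queue <- queue[-1L]
    can0 <- bitwOr(notx, W)
    can1 <- bitwOr(x, W)
    imgs <- ms_images(cp, can0, can1)
    Ws <- c(Ws, W)
    img0s <- c(img0s, imgs$img0)
    img1s <- c(img1s, imgs$img1)
    # nodes whose image contains the value opposite to x_i can widen
    want <- bitwOr(bitwAnd(imgs$img0, x), bitwAnd(imgs$img1, notx))
    want <- bitwAnd(bitwAnd(want, free), bitwXor(cp$full, W))
    for (b in cp$bits) {
      if (bitwAnd(want, b) == 0L) next
      W2 <- bitwOr(W, b)
      k2 <- as.character(W2)
      if (is.null(seen[[k2]])) {
        seen[[k2]] <- TRUE
        queue <- c(queue, W2)
      }
    }
  }
  list(x = x, Ws = Ws, img0s = img0s, img1s = img1s)
}

# Support-consistency test against a closure, for a (possibly partial) target
# (obs mask/value). Vectorized over all meta-states in the closure.
sc_check <- function(clo, full, obsmask, obsval) {
  x <- clo$x
  xy_diff <- bitwAnd(bitwXor(x, obsval), obsmask)
  # membership: y may differ from x only on widened components
  member <- bitwAnd(xy_diff, bitwXor(full, clo$Ws)) == 0L
  if (!any(member)) return(FALSE)
  same <- bitwAnd(bitwXor(xy_diff, full), obsmask)
  image_ok <- bitwOr(
    bitwAnd(obsval, clo$img1s),
    bitwAnd(bitwAnd(bitwXor(obsval, full), obsmask), clo$img0s)
  )
  fail <- bitwAnd(bitwAnd(same, clo$Ws), bitwXor(full, image_ok))
  any(member & fail == 0L)
}

# Maximal widening set from the singleton meta-state of x: the greedy fixpoint
# adding every widenable component at once. Because the per-node image is
# monotone in the meta-state, (i) every reachable meta-state is below W*, and
# (ii) W* itself is reachable one component at a time.
greedy_wstar <- function(cp, x, clampmask) {
  notx <- bitwXor(x, cp$full)
  free <- bitwXor(cp$full, clampmask)
  W <- 0L
  repeat {
    imgs <- ms_images(cp, bitwOr(notx, W), bitwOr(x, W))
    want <- bitwOr(bitwAnd(imgs$img0, x), bitwAnd(imgs$img1, notx))
    want <- bitwAnd(bitwAnd(want, free), bitwXor(cp$full, W))
    if (want == 0L) break
    W <- bitwOr(W, want)
  }
  list(W = W, img0 = imgs$img0, img1 = imgs$img1)
}

# Exact support-consistency query with fast paths. Decides most queries from
# W* alone: a target flipping a bit outside W* can never be support-consistent
# (all reachable meta-states are below W*), and a target passing all three
# conditions at W* is certified because W* is reachable. Only the remaining
# ambiguous cases fall back to the full meta-closure.
sc_query <- function(cp, x, clampmask, clampval, obsmask, obsval) {
  ws <- greedy_wstar(cp, x, clampmask)
  diff <- bitwAnd(bitwXor(x, obsval), obsmask)
  if (bitwAnd(diff, bitwXor(cp$full, ws$W)) != 0L) return(FALSE)
  same <- bitwAnd(bitwXor(bitwXor(x, obsval), cp$full), obsmask)
  image_ok <- bitwOr(
    bitwAnd(obsval, ws$img1),
    bitwAnd(bitwAnd(bitwXor(obsval, cp$full), obsmask), ws$img0)
  )
  fail <- bitwAnd(bitwAnd(same, ws$W), bitwXor(cp$full, image_ok))
  if (fail == 0L) return(TRUE)
  clo <- meta_closure(cp, x, clampmask, clampval)
  sc_check(clo, cp$full, obsmask, obsval)
}

# Vectorized sc_query over many full target states: W* fast paths first,
# full-closure fallback only for the ambiguous remainder.
sc_query_many <- function(cp, x, clampmask, clampval, ys) {
  ws <- greedy_wstar(cp, x, clampmask)
  full <- cp$full
  diff <- bitwXor(x, ys)
  possible <- bitwAnd(diff, bitwXor(full, ws$W)) == 0L
  same <- bitwXor(diff, full)
  image_ok <- bitwOr(
    bitwAnd(ys, ws$img1),
    bitwAnd(bitwXor(ys, full), ws$img0)
  )
  fail <- bitwAnd(bitwAnd(same, ws$W), bitwXor(full, image_ok))
  out <- possible & fail == 0L
  todo <- which(possible & fail != 0L)
  if (length(todo) > 0L) {
    clo <- meta_closure(cp, x, clampmask, clampval)
    out[todo] <- sc_check_many(clo, full, ys[todo])
  }
  out
}

# Bulk variant of sc_check: one closure against a vector of full target
# states. Loops over the closure's meta-states (few) and vectorizes over the
# targets (many).
sc_check_many <- function(clo, full, ys) {
  x <- clo$x
  ok <- rep(FALSE, length(ys))
  notys <- bitwXor(ys, full)
  for (i in seq_along(clo$Ws)) {
    W <- clo$Ws[i]
    todo <- !ok
    if (!any(todo)) break
    member <- bitwAnd(bitwXor(x, ys), bitwXor(full, W)) == 0L
    same <- bitwXor(bitwXor(x, ys), full)
    image_ok <- bitwOr(
      bitwAnd(ys, clo$img1s[i]),
      bitwAnd(notys, clo$img0s[i])
    )
    fail <- bitwAnd(bitwAnd(same, W), bitwXor(full, image_ok))
    ok <- ok | (member & fail == 0L)
  }
  ok
}

#' Support consistency: a necessary condition for reachability
#'
#' `y` is support-consistent with `x` when some meta-state `u`, reachable from
#' the singleton meta-state of `x` by zero or more widening steps, contains
#' `y` and additionally satisfies, for every component `i` that `y`
#' constrains: (a) `y_i != x_i`, or (b) `y_i = x_i` and `u_i != {0,1}`, or
#' (c) `y_i = x_i`, `u_i = {0,1}`, and some state `z` in `u` has
#' `f_i(z) = y_i`. Exact reachability implies support consistency, but not
#' conversely — the gap is what separates true-positive from false-positive
#' learned networks.
#'
#' @inheritParams reachable
#' @param y Full or partial named 0/1 state vector.
#' @return `TRUE` or `FALSE`.
#' @export
support_consistent <- function(bn, x, y, clamp = NULL) {
  cp <- compile_bn(bn)
  cl <- pack_clamp(clamp %||% integer(0), bn$nodes)
  xi <- pack_state(x, bn$nodes)
  check_clamp_respected(xi, cl$mask, cl$value)
  p <- pack_partial(y, bn$nodes)
  clo <- meta_closure(cp, xi, cl$mask, cl$value)
  sc_check(clo, cp$full, p$mask, p$value)
}

# ---- clampings -------------------------------------------------------------

#' Clamping induced by a perturbation
#'
#' A perturbation fixes the experimental handles for the whole trajectory:
#' every stimulus is clamped at its 0/1 setting, and every inhibitor whose
#' setting is 1 (inhibitor applied) is clamped at 0. Inhibitors not applied
#' are left free.
#'
#' @param settings Named 0/1 vector over stimuli and inhibitors (the
#'   perturbation row).
#' @param roles Named role vector (as in a `pkn`), used to tell stimuli from
#'   inhibitors.
#' @return Named 0/1 integer vector of clamped nodes.
#' @export
clamping <- function(settings, roles) {
  if (length(settings) == 0L) return(setNames(integer(0), character(0)))
  stopifnot(!is.null(names(settings)))
  out <- integer(0)
  for (nd in names(settings)) {
    r <- roles[[nd]]
    if (is.null(r) || is.na(r)) stop("no role known for treated node ", nd, call. = FALSE)
    if (r == "stimulus") {
      out[nd] <- as.integer(settings[[nd]])
    } else if (r %in% c("inhibitor", "inhibitor_and_readout")) {
      if (settings[[nd]] == 1) out[nd] <- 0L
    } else {
      stop("treated node ", nd, " is neither stimulus nor inhibitor", call. = FALSE)
    }
  }
  out
}
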