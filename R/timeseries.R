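#' Multi-perturbation time-series datasets
#'
#' The canonical container for perturbation screening data: a long measurement
#' table (one row per perturbation, time point and observed node) plus the
#' treatment settings of each perturbation. Values are expected in \[0,1\]
#' after [normalize()]; `NA` marks missing readings until [qc_repair()] deals
#' with them.
#'
#' @param measurements Data frame with columns `perturbation`, `time`, `node`,
#'   `value`.
#' @param perturbations Data frame with columns `perturbation`, `node`,
#'   `value` giving the 0/1 setting of every treated (stimulus/inhibitor)
#'   node under each perturbation.
#' @param binarized Logical; `TRUE` when values are 0/1 codes rather than
#'   continuous measurements.
#' @return An object of class `pert_ts`.
#' @export
pert_ts <- function(measurements, perturbations, binarized = FALSE) {
  m <- as_tibble(measurements)
  p <- as_tibble(perturbations)
  if (!all(c("perturbation", "time", "node", "value") %in% names(m))) {
    stop("measurements need columns perturbation, time, node, value", call. = FALSE)
  }
  if (!all(c("perturbation", "node", "value") %in% names(p))) {
    stop("perturbations need columns perturbation, node, value", call. = FALSE)
  }
  m <- m %>%
    mutate(
      perturbation = as.character(perturbation), node = as.character(node),
      time = as.numeric(time), value = as.numeric(value)
    ) %>%
    select(perturbation, time, node, value)
  p <- p %>%
    mutate(
      perturbation = as.character(perturbation), node = as.character(node),
      value = as.integer(value)
    ) %>%
    select(perturbation, node, value)
  if (!all(p$value %in% c(0L, 1L))) {
    stop("perturbation settings must be 0/1", call. = FALSE)
  }
  orphan <- setdiff(m$perturbation, p$perturbation)
  if (length(orphan) > 0L) {
    stop("measurements reference unknown perturbation(s): ",
      paste(orphan, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(measurements = m, perturbations = p, binarized = isTRUE(binarized)),
    class = "pert_ts"
  )
}

#' @export
print.pert_ts <- function(x, ...) {
  cat(sprintf(
    "<pert_ts%s> %d perturbations x %d time points x %d observed nodes (%d missing values)\n",
    if (x$binarized) " binarized" else "",
    length(pts_perturbations(x)), length(pts_timepoints(x)),
    length(pts_observed(x)), sum(is.na(x$measurements$value))
  ))
  invisible(x)
}

#' Accessors for `pert_ts` objects
#'
#' @param x A `pert_ts`.
#' @return `pts_perturbations`: perturbation ids (in first-appearance order);
#'   `pts_timepoints`: sorted time labels; `pts_observed`: observed node
#'   names (first-appearance order); `pts_settings`: named 0/1 vector of one
#'   perturbation's treatments.
#' @export
pts_perturbations <- function(x) unique(x$perturbations$perturbation)

#' @rdname pts_perturbations
#' @export
pts_timepoints <- function(x) sort(unique(x$measurements$time))

#' @rdname pts_perturbations
#' @export
pts_observed <- function(x) unique(x$measurements$node)

#' @rdname pts_perturbations
#' @param perturbation A perturbation id.
#' @export
pts_settings <- function(x, perturbation) {
  p <- x$perturbations[x$perturbations$perturbation == perturbation, ]
  setNames(p$value, p$node)
}

#' @export
tidy.pert_ts <- function(x, ...) x$measurements

#' @export
glance.pert_ts <- function(x, ...) {
  tibble(
    n_perturbations = length(pts_perturbations(x)),
    n_timepoints = length(pts_timepoints(x)),
    n_observed = length(pts_observed(x)),
    n_missing = sum(is.na(x$measurements$value)),
    binarized = x$binarized
  )
}

# Strict shape check used by normalize/binarize/learn: complete grid, no
# perturbation-specific time axes or node sets.
validate_pert_ts <- function(x, allow_missing = TRUE) {
  stopifnot(inherits(x, "pert_ts"))
  m <- x$measurements
  grid <- tidyr::expand_grid(
    perturbation = pts_perturbations(x),
    time = pts_timepoints(x),
    node = pts_observed(x)
  )
  if (nrow(m) != nrow(grid) || nrow(dplyr::anti_join(grid, m,
    by = c("perturbation", "time", "node")
  )) > 0L) {
    stop("dataset is not a complete perturbation x time x node grid; run qc_repair()",
      call. = FALSE
    )
  }
  if (!allow_missing && anyNA(m$value)) {
    bad <- m[is.na(m$value), ][1, ]
    stop(sprintf(
      "missing value at (%s, t=%s, %s)", bad$perturbation, bad$time, bad$node
    ), call. = FALSE)
  }
  invisible(x)
}

#' Maximum-value normalization
#'
#' Divides every measurement of a node by that node's global maximum across
#' all perturbations and time points, mapping each observed node onto a common
#' \[0,1\] scale in which its peak is exactly 1. Missing entries stay missing.
#' Idempotent.
#'
#' @param x A `pert_ts` with non-negative raw values.
#' @return A normalized `pert_ts`.
#' @export
normalize <- function(x) {
  validate_pert_ts(x)
  if (x$binarized) stop("dataset is already binarized", call. = FALSE)
  m <- x$measurements
  if (any(m$value < 0, na.rm = TRUE)) stop("raw values must be >= 0", call. = FALSE)
  mx <- tapply(m$value, m$node, function(v) suppressWarnings(max(v, na.rm = TRUE)))
  bad <- names(mx)[!is.finite(mx) | mx == 0]
  if (length(bad) > 0L) {
    stop("cannot normalize node(s) with zero (or undefined) global maximum: ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  m$value <- as.numeric(m$value / unname(mx[m$node]))
  out <- x
  out$measurements <- m
  out
}

#' Binarize a normalized dataset
#'
#' Maps each value to 1 when `value >= threshold`, else 0 (ties go to 1).
#'
#' @param x A normalized `pert_ts` without missing entries.
#' @param threshold Binarization cutoff in (0,1); default 0.5, the midpoint of
#'   the normalized scale.
#' @return A binarized `pert_ts`.
#' @export
binarize <- function(x, threshold = 0.5) {
  validate_pert_ts(x, allow_missing = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  if (any(x$measurements$value < 0 | x$measurements$value > 1)) {
    stop("values must be in [0,1]; normalize first", call. = FALSE)
  }
  out <- x
  out$measurements$value <- as.numeric(x$measurements$value >= threshold)
  out$binarized <- TRUE
  out
}

#' Quality control and repair of raw perturbation series
#'
#' Applies, in order, the four structural repair rules used on real
#' perturbation screens:
#' \describe{
#'   \item{step-2}{missing time-0 readings are filled from control readings
#'     (untreated measurements of each node), when available;}
#'   \item{step-3}{duplicated readings of one (perturbation, time, node) cell
#'     keep the first value in file order;}
#'   \item{step-4}{perturbations in which an applied inhibitor is itself
#'     measured and shows dynamic behaviour — (max - min) of its trace on the
#'     per-node-max normalized scale exceeds `tolerance` — are dropped as
#'     experimentally inconsistent (the inhibited protein should stay flat);}
#'   \item{step-5}{perturbations still containing missing values are dropped
#'     (no imputation).}
#' }
#' Nothing raises: every repair or drop becomes a report row, and an empty
#' surviving dataset is reported, not an error.
#'
#' @param x A raw `pert_ts`.
#' @param roles Named role vector (or a `pkn`) identifying inhibitors.
#' @param control Optional control readings for step-2: named numeric vector
#'   or data frame with columns `node`, `value`.
#' @param tolerance Step-4 flatness tolerance on the normalized scale
#'   (default 0.1).
#' @return A list with elements `data` (repaired `pert_ts`) and `report`
#'   (tibble with columns `rule`, `perturbation`, `time`, `node`, `action`,
#'   `value`). Replaying the report on the input reproduces the output (see
#'   [qc_replay()]).
#' @export
qc_repair <- function(x, roles, control = NULL, tolerance = 0.1) {
  stopifnot(inherits(x, "pert_ts"), tolerance >= 0)
  if (inherits(roles, "pkn")) roles <- roles$roles
  if (is.data.frame(control)) control <- setNames(control$value, control$node)
  report <- tibble(
    rule = character(), perturbation = character(), time = numeric(),
    node = character(), action = character(), value = numeric()
  )
  m <- x$measurements
  t0 <- min(m$time)
  timepoints <- sort(unique(m$time))
  nodes <- unique(m$node)

  # step-3 first in mechanics (dedup makes the grid well-defined) but rows are
  # reported under their own rule id; keep first occurrence in file order.
  dup <- duplicated(m[, c("perturbation", "time", "node")])
  if (any(dup)) {
    report <- bind_rows(report, tibble(
      rule = "step-3", perturbation = m$perturbation[dup], time = m$time[dup],
      node = m$node[dup], action = "dropped_duplicate", value = m$value[dup]
    ))
    m <- m[!dup, ]
  }

  # complete the grid so absent cells become explicit NAs
  m <- tidyr::complete(m,
    perturbation = unique(m$perturbation), time = timepoints, node = nodes
  ) %>% select(perturbation, time, node, value)

  # step-2: fill missing t0 from control
  if (!is.null(control)) {
    idx <- which(m$time == t0 & is.na(m$value) & m$node %in% names(control))
    if (length(idx) > 0L) {
      filled <- unname(control[m$node[idx]])
      report <- bind_rows(report, tibble(
        rule = "step-2", perturbation = m$perturbation[idx], time = m$time[idx],
        node = m$node[idx], action = "filled_from_control", value = filled
      ))
      m$value[idx] <- filled
    }
  }

  # step-4: applied inhibitor with dynamic readout trace => drop perturbation
  inhibitors <- names(roles)[roles %in% c("inhibitor", "inhibitor_and_readout")]
  mx <- tapply(m$value, m$node, function(v) suppressWarnings(max(v, na.rm = TRUE)))
  drop4 <- character(0)
  for (p in unique(m$perturbation)) {
    applied <- x$perturbations %>%
      filter(perturbation == p, value == 1L, node %in% inhibitors) %>%
      pull(node)
    for (nd in intersect(applied, nodes)) {
      tr <- m$value[m$perturbation == p & m$node == nd]
      tr <- tr[!is.na(tr)]
      if (length(tr) < 2L || !is.finite(mx[[nd]]) || mx[[nd]] == 0) next
      rng <- (max(tr) - min(tr)) / mx[[nd]]
      if (rng > tolerance) {
        drop4 <- c(drop4, p)
        report <- bind_rows(report, tibble(
          rule = "step-4", perturbation = p, time = NA_real_, node = nd,
          action = "dropped_perturbation", value = rng
        ))
      }
    }
  }
  m <- m[!(m$perturbation %in% drop4), ]

  # step-5: drop perturbations with remaining missing points
  incomplete <- unique(m$perturbation[is.na(m$value)])
  if (length(incomplete) > 0L) {
    report <- bind_rows(report, tibble(
      rule = "step-5", perturbation = incomplete, time = NA_real_,
      node = NA_character_, action = "dropped_perturbation", value = NA_real_
    ))
    m <- m[!(m$perturbation %in% incomplete), ]
  }

  out <- x
  out$measurements <- m
  out$perturbations <- x$perturbations %>%
    filter(perturbation %in% unique(m$perturbation))
  if (nrow(m) == 0L) {
    report <- bind_rows(report, tibble(
      rule = "empty", perturbation = NA_character_, time = NA_real_,
      node = NA_character_, action = "empty_dataset", value = NA_real_
    ))
  }
  list(data = out, report = report)
}

#' Replay a QC report
#'
#' Reconstructs the output of [qc_repair()] from its input and report alone,
#' which is how the report's exhaustiveness is checked.
#'
#' @param x The raw `pert_ts` given to [qc_repair()].
#' @param report The report it returned.
#' @return A repaired `pert_ts`.
#' @export
qc_replay <- function(x, report) {
  m <- x$measurements
  dup <- duplicated(m[, c("perturbation", "time", "node")])
  m <- m[!dup, ]
  m <- tidyr::complete(m,
    perturbation = unique(m$perturbation),
    time = sort(unique(x$measurements$time)),
    node = unique(x$measurements$node)
  ) %>% select(perturbation, time, node, value)
  fills <- report[report$rule == "step-2", ]
  for (i in seq_len(nrow(fills))) {
    sel <- m$perturbation == fills$perturbation[i] & m$time == fills$time[i] &
      m$node == fills$node[i]
    m$value[sel] <- fills$value[i]
  }
  drops <- unique(report$perturbation[report$action == "dropped_perturbation"])
  m <- m[!(m$perturbation %in% drops), ]
  out <- x
  out$measurements <- m
  out$perturbations <- x$perturbations %>%
    filter(perturbation %in% unique(m$perturbation))
  out
}
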