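#' Run the full learning workflow
#'
#' The two-step workflow on one dataset: quality control and normalization,
#' RMSE-optimal learning under the over-approximation constraint, exact
#' certification of every optimal network (TP/FP triage), and family
#' aggregation of the certified networks.
#'
#' @param x A `pkn`.
#' @param raw A raw `pert_ts` (e.g. from [read_midas()] or
#'   [simulate_dataset()]).
#' @param control Optional control readings for QC step 2.
#' @param tolerance QC step-4 flatness tolerance. The default 0.4 suits
#'   band-coded signals (as emitted by [simulate_dataset()]), whose static
#'   traces already jitter within a 0.3-wide band: only swings beyond one
#'   band width are treated as genuine dynamics of an inhibited protein.
#' @param config A [learn_config()].
#' @param threshold Binarization threshold.
#' @param verify_budget States explored per network during certification.
#' @param aggregate_threshold Frequency cutoff for the aggregated network.
#' @param label Family label.
#' @return A list of class `bn_pipeline` with elements `qc` (report), `data`
#'   (normalized QC'd dataset), `fit` (`bn_learn`), `triage` (verdict tibble),
#'   `tp_family` (certified family, `NULL` if no TP), `aggregate` (of the TP
#'   family or, failing that, of all optimal networks), and `manifest` (run
#'   summary tibble).
#' @export
run_pipeline <- function(x, raw, control = attr(raw, "control"),
                         tolerance = 0.4, config = learn_config(),
                         threshold = 0.5, verify_budget = 2^20,
                         aggregate_threshold = 0.3, label = "run") {
  stopifnot(inherits(x, "pkn"), inherits(raw, "pert_ts"))
  qc <- qc_repair(raw, x$roles, control = control, tolerance = tolerance)
  if (nrow(qc$data$measurements) == 0L) {
    stop("no perturbation survived quality control", call. = FALSE)
  }
  norm <- normalize(qc$data)
  fit <- learn(x, norm, config = config, threshold = threshold)
  tri <- triage(fit, x$roles, budget_per_bn = verify_budget)
  tp_idx <- which(tri$status == "TP")
  tp_family <- if (length(tp_idx) > 0L) {
    bn_family(map(fit$results[tp_idx], "bn"), label = label)
  } else {
    NULL
  }
  fam <- tp_family %||% bn_family(map(fit$results, "bn"), label = label)
  agg <- aggregate_family(fam, threshold = aggregate_threshold)
  manifest <- tibble(
    label = label,
    n_perturbations = length(pts_perturbations(norm)),
    n_timepoints = length(pts_timepoints(norm)),
    n_observed = length(pts_observed(norm)),
    n_models = length(fit$results),
    n_tp = sum(tri$status == "TP"),
    n_fp = sum(tri$status == "FP"),
    n_undecided = sum(tri$status == "undecided"),
    model_rmse = fit$objective,
    discrete_rmse = fit$discrete_rmse,
    rmse_ratio = rmse_ratio(fit$discrete_rmse, fit$objective),
    proven_optimal = fit$proven_optimal,
    seed = config$seed
  )
  structure(list(
    qc = qc$report, data = norm, fit = fit, triage = tri,
    tp_family = tp_family, aggregate = agg, manifest = manifest
  ), class = "bn_pipeline")
}

#' @export
print.bn_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<bn_pipeline '%s'> %d model(s): %d TP / %d FP / %d undecided; model RMSE %.4f (floor %.4f)\n",
    m$label, m$n_models, m$n_tp, m$n_fp, m$n_undecided, m$model_rmse, m$discrete_rmse
  ))
  invisible(x)
}

#' @export
glance.bn_pipeline <- function(x, ...) x$manifest
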