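#' Read and write MIDAS-dialect tables
#'
#' The MIDAS dialect used for perturbation screens: one row per (perturbation,
#' time) record, with treatment columns `TR:<name>:Stimuli` (stimulus 0/1) and
#' `TR:<name>i` (inhibitor applied 0/1), the time column `DA:ALL`, and one
#' measurement column `DV:<name>` per readout. Empty `DV` cells are missing
#' values. Perturbation ids are assigned per unique treatment combination in
#' file order (`p01`, `p02`, ...).
#'
#' Node roles are inferred from the header (stimulus/inhibitor from `TR`
#' columns, readout from `DV`; a node that is both inhibited and measured gets
#' `inhibitor_and_readout`) and attached as `attr(x, "roles")`.
#'
#' @param path CSV file path.
#' @return `read_midas`: a [pert_ts()] with a `roles` attribute.
#' @export
read_midas <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "d"), progress = FALSE)
  cn <- names(df)
  stim_cols <- grep("^TR:.*:Stimuli$", cn, value = TRUE)
  inhib_cols <- grep("^TR:.*i$", cn, value = TRUE)
  inhib_cols <- setdiff(inhib_cols, stim_cols)
  dv_cols <- grep("^DV:", cn, value = TRUE)
  if (!"DA:ALL" %in% cn) stop("MIDAS file lacks DA:ALL time column", call. = FALSE)
  if (length(dv_cols) == 0L) stop("MIDAS file has no DV: columns", call. = FALSE)
  stim_nodes <- sub("^TR:(.*):Stimuli$", "\\1", stim_cols)
  inhib_nodes <- sub("^TR:(.*)i$", "\\1", inhib_cols)
  dv_nodes <- sub("^DV:", "", dv_cols)

  tr <- df[, c(stim_cols, inhib_cols), drop = FALSE]
  combo <- do.call(paste, c(tr, sep = "|"))
  pid <- sprintf("p%02d", match(combo, unique(combo)))

  meas <- df[, c("DA:ALL", dv_cols)]
  names(meas) <- c("time", dv_nodes)
  meas$perturbation <- pid
  measurements <- tidyr::pivot_longer(meas, -c(time, perturbation),
    names_to = "node", values_to = "value"
  )

  settings <- tr
  names(settings) <- c(stim_nodes, inhib_nodes)
  settings$perturbation <- pid
  perturbations <- settings %>%
    distinct() %>%
    tidyr::pivot_longer(-perturbation, names_to = "node", values_to = "value")

  roles <- c(
    setNames(rep("stimulus", length(stim_nodes)), stim_nodes),
    setNames(
      ifelse(inhib_nodes %in% dv_nodes, "inhibitor_and_readout", "inhibitor"),
      inhib_nodes
    ),
    setNames(rep("readout", length(setdiff(dv_nodes, inhib_nodes))),
      setdiff(dv_nodes, inhib_nodes)
    )
  )
  out <- pert_ts(measurements, perturbations)
  attr(out, "roles") <- roles
  out
}

#' @rdname read_midas
#' @param x A `pert_ts`.
#' @param roles Named role vector distinguishing stimuli from inhibitors among
#'   the treated nodes; defaults to the object's `roles` attribute.
#' @return `write_midas`: `path`, invisibly.
#' @export
write_midas <- function(x, path, roles = attr(x, "roles")) {
  stopifnot(inherits(x, "pert_ts"))
  if (is.null(roles)) stop("roles needed to name TR columns", call. = FALSE)
  treated <- unique(x$perturbations$node)
  stim <- intersect(treated, names(roles)[roles == "stimulus"])
  inhib <- setdiff(treated, stim)
  # a node may be both treated and measured (inhibitor_and_readout), so the
  # treatment and measurement tables are kept apart and matched by id
  wide_tr <- x$perturbations %>%
    tidyr::pivot_wider(names_from = node, values_from = value)
  wide_dv <- x$measurements %>%
    tidyr::pivot_wider(names_from = node, values_from = value)
  obs <- pts_observed(x)
  idx <- match(wide_dv$perturbation, wide_tr$perturbation)
  out <- tibble(.rows = nrow(wide_dv))
  for (s in stim) out[[paste0("TR:", s, ":Stimuli")]] <- wide_tr[[s]][idx]
  for (i in inhib) out[[paste0("TR:", i, "i")]] <- wide_tr[[i]][idx]
  out[["DA:ALL"]] <- wide_dv$time
  for (r in obs) out[[paste0("DV:", r)]] <- wide_dv[[r]]
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
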