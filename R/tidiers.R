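#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PKN into its edge table
#'
#' @param x A `pkn`.
#' @param ... Unused.
#' @return Tibble with columns `source`, `sign`, `target`, plus `source_role`
#'   and `target_role`.
#' @export
tidy.pkn <- function(x, ...) {
  x$edges %>%
    mutate(
      source_role = unname(x$roles[source]),
      target_role = unname(x$roles[target])
    )
}

#' @rdname tidy.pkn
#' @export
glance.pkn <- function(x, ...) {
  r <- x$roles
  tibble(
    n_nodes = length(x$nodes),
    n_edges = nrow(x$edges),
    n_stimuli = sum(r == "stimulus"),
    n_inhibitors = sum(r %in% c("inhibitor", "inhibitor_and_readout")),
    n_readouts = sum(r %in% c("readout", "inhibitor_and_readout")),
    n_unobserved = sum(r == "unobserved")
  )
}

#' Tidy a Boolean network into its hyper-edge table
#'
#' @param x A `boolean_network`.
#' @param ... Unused.
#' @return Tibble with one row per hyper-edge (`target`, `clause`,
#'   `hyperedge`).
#' @export
tidy.boolean_network <- function(x, ...) bn_hyperedges(x)

#' @rdname tidy.boolean_network
#' @export
glance.boolean_network <- function(x, ...) {
  he <- bn_hyperedges(x)
  tibble(
    n_nodes = length(x$nodes),
    n_hyperedges = nrow(he),
    n_regulated = dplyr::n_distinct(he$target),
    n_and_gates = sum(grepl("&", he$clause, fixed = TRUE))
  )
}
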