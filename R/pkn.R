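#' Prior knowledge networks
#'
#' A prior knowledge network (PKN) is a signed directed graph over proteins
#' (or any named species) together with a role for each node: `stimulus`
#' (experimentally set to 0/1), `inhibitor` (can be clamped to 0),
#' `readout` (measured in \[0,1\]), `inhibitor_and_readout` (both — the only
#' permitted overlap), or `unobserved`. The PKN is the structural prior that
#' every candidate Boolean network must be compatible with.
#'
#' @param edges A data frame with columns `source`, `sign` (+1 or -1) and
#'   `target`, one row per signed edge. Parallel edges with opposite signs are
#'   allowed; exact duplicates are not.
#' @param roles Either `NULL` (every node `unobserved`), a named character
#'   vector (`node = role`), or a data frame with columns `node` and `role`.
#'   Nodes listed with both `inhibitor` and `readout` roles are merged into
#'   `inhibitor_and_readout`; any other duplicated role assignment is an error.
#' @param nodes Optional full node universe; defaults to the edge endpoints.
#'   Must contain every endpoint; extra entries are isolated nodes.
#' @return An object of class `pkn` with fields `edges` (tibble), `roles`
#'   (named character vector over all nodes) and `nodes` (character vector in
#'   first-appearance order).
#' @examples
#' edges <- tibble::tibble(
#'   source = c("egf", "egf", "ras"),
#'   sign   = c(1, 1, -1),
#'   target = c("ras", "akt", "akt")
#' )
#' net <- pkn(edges, roles = c(egf = "stimulus", akt = "readout"))
#' glance(net)
#' @seealso [read_sif()], [clause_space()]
#' @export
pkn <- function(edges, roles = NULL, nodes = NULL) {
  edges <- as_tibble(edges)
  need <- c("source", "sign", "target")
  if (!all(need %in% names(edges))) {
    stop("`edges` must have columns source, sign, target", call. = FALSE)
  }
  edges <- edges %>%
    mutate(
      source = as.character(source),
      target = as.character(target),
      sign = as.integer(sign)
    ) %>%
    select(source, sign, target)
  if (!all(edges$sign %in% c(-1L, 1L))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  if (anyDuplicated(edges)) {
    stop("duplicate (source, target, sign) triples in edge list", call. = FALSE)
  }
  endpoints <- unique(c(edges$source, edges$target))
  if (is.null(nodes)) {
    nodes <- endpoints
  } else {
    nodes <- as.character(nodes)
    missing_ep <- setdiff(endpoints, nodes)
    if (length(missing_ep) > 0L) {
      stop("edge endpoint(s) not in declared nodes: ",
        paste(missing_ep, collapse = ", "),
        call. = FALSE
      )
    }
  }
  roles <- normalize_roles(roles, nodes)
  structure(list(edges = edges, roles = roles, nodes = nodes), class = "pkn")
}

pkn_role_levels <- c(
  "stimulus", "inhibitor", "readout", "inhibitor_and_readout", "unobserved"
)

normalize_roles <- function(roles, nodes) {
  if (is.null(roles)) {
    return(setNames(rep("unobserved", length(nodes)), nodes))
  }
  if (is.data.frame(roles)) {
    rl <- as_tibble(roles)
    if (!all(c("node", "role") %in% names(rl))) {
      stop("role table must have columns node, role", call. = FALSE)
    }
    pairs <- split(as.character(rl$role), as.character(rl$node))
    roles <- vapply(pairs, function(rs) {
      rs <- unique(rs)
      if (length(rs) == 1L) return(rs)
      if (setequal(rs, c("inhibitor", "readout"))) return("inhibitor_and_readout")
      stop("conflicting roles for one node: ", paste(rs, collapse = "/"),
        call. = FALSE
      )
    }, character(1))
  }
  roles <- setNames(as.character(roles), names(roles))
  unknown <- setdiff(names(roles), nodes)
  if (length(unknown) > 0L) {
    stop("role assigned to unknown node(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(roles, pkn_role_levels)
  if (length(bad) > 0L) {
    stop("unknown role(s): ", paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  out <- setNames(rep("unobserved", length(nodes)), nodes)
  out[names(roles)] <- roles
  out
}

#' @export
print.pkn <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<pkn> %d nodes, %d edges (%d stimuli, %d inhibitors, %d readouts, %d unobserved)\n",
    g$n_nodes, g$n_edges, g$n_stimuli, g$n_inhibitors, g$n_readouts, g$n_unobserved
  ))
  invisible(x)
}

#' Nodes of a PKN or Boolean network with a given role
#'
#' @param x A `pkn` object.
#' @param role One of `"stimulus"`, `"inhibitor"`, `"readout"`,
#'   `"unobserved"`. Inhibitor-and-readout nodes count as both inhibitors and
#'   readouts.
#' @return Character vector of node names.
#' @export
pkn_nodes <- function(x, role = NULL) {
  stopifnot(inherits(x, "pkn"))
  if (is.null(role)) return(x$nodes)
  r <- x$roles
  switch(role,
    stimulus = names(r)[r == "stimulus"],
    inhibitor = names(r)[r %in% c("inhibitor", "inhibitor_and_readout")],
    readout = names(r)[r %in% c("readout", "inhibitor_and_readout")],
    unobserved = names(r)[r == "unobserved"],
    stop("unknown role: ", role, call. = FALSE)
  )
}

#' Read a signed interaction (SIF-style) network file
#'
#' Each non-empty line is `source <sign> target`, whitespace- or tab-separated.
#' Accepted sign tokens: `1`, `+1`, `activate` for activation and `-1`,
#' `inhibit` for inhibition.
#'
#' @param path Path to the network file.
#' @param roles Role assignment as in [pkn()]; may also be a path to a
#'   two-column (node, role) whitespace-separated table.
#' @return A [pkn()] object.
#' @export
read_sif <- function(path, roles = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("empty network file: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(parts) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: %s", keep[bad[1]], path, lines[keep[bad[1]]]),
      call. = FALSE
    )
  }
  sign_tok <- vapply(parts, `[[`, character(1), 2L)
  sgn <- dplyr::case_match(tolower(sign_tok),
    c("1", "+1", "activate") ~ 1L,
    c("-1", "inhibit") ~ -1L,
    .default = NA_integer_
  )
  if (anyNA(sgn)) {
    i <- which(is.na(sgn))[1]
    stop(sprintf("malformed line %d in %s: unrecognized sign token '%s'",
      keep[i], path, sign_tok[i]
    ), call. = FALSE)
  }
  if (is.character(roles) && length(roles) == 1L && is.null(names(roles)) &&
    file.exists(roles)) {
    roles <- readr::read_table(roles,
      col_names = c("node", "role"),
      col_types = "cc", progress = FALSE
    )
  }
  pkn(
    tibble(
      source = vapply(parts, `[[`, character(1), 1L),
      sign = sgn,
      target = vapply(parts, `[[`, character(1), 3L)
    ),
    roles = roles
  )
}

#' Write a PKN to a SIF-style file
#'
#' @param x A `pkn` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(x, path) {
  stopifnot(inherits(x, "pkn"))
  writeLines(sprintf("%s\t%+d\t%s", x$edges$source, x$edges$sign, x$edges$target), path)
  invisible(path)
}

#' Sign-consistent clause space of a PKN
#'
#' For each node, enumerates every admissible conjunctive clause over its
#' direct PKN predecessors: a literal is positive when the corresponding edge
#' is activating and negated when it is inhibiting, a clause never contains
#' both polarities of one regulator, and clause size is capped. Candidate
#' Boolean networks are disjunctions of these clauses, so the clause space
#' concretizes "compatible with the PKN".
#'
#' Clauses are canonically ordered (by size, then lexicographically by their
#' printed form) so enumeration downstream is deterministic.
#'
#' @param x A `pkn` object.
#' @param max_clause_size Maximum number of literals per clause (default 2).
#' @return A tibble with columns `target`, `clause` (printed form, e.g.
#'   `"a&!b"`), `size`, and `literals` (list column of named +1/-1 integer
#'   vectors). Nodes without predecessors contribute no rows.
#' @examples
#' net <- pkn(tibble::tibble(
#'   source = c("p", "q"), sign = c(1, -1), target = c("r", "r")
#' ))
#' clause_space(net) # {p}, {!q}, {p & !q}
#' @export
clause_space <- function(x, max_clause_size = 2L) {
  stopifnot(inherits(x, "pkn"), max_clause_size >= 1L)
  by_target <- split(x$edges, x$edges$target)
  rows <- lapply(names(by_target), function(tg) {
    ed <- by_target[[tg]]
    lits <- distinct(tibble(reg = ed$source, sign = ed$sign)) %>%
      arrange(reg, sign)
    d <- length(unique(lits$reg))
    cap <- min(nrow(lits), max_clause_size)
    combos <- unlist(lapply(seq_len(cap), function(s) {
      cm <- combn(nrow(lits), s, simplify = FALSE)
      # exclude clauses using one regulator with both polarities
      keep(cm, function(ix) !anyDuplicated(lits$reg[ix]))
    }), recursive = FALSE)
    if (length(combos) == 0L) return(NULL)
    literals <- lapply(combos, function(ix) {
      setNames(lits$sign[ix], lits$reg[ix])
    })
    tibble(
      target = tg,
      clause = vapply(literals, format_clause, character(1)),
      size = lengths(literals),
      literals = literals
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(
      target = character(), clause = character(),
      size = integer(), literals = list()
    ))
  }
  out %>%
    arrange(target, size, clause) %>%
    group_by(target) %>%
    mutate(clause_id = row_number()) %>%
    ungroup() %>%
    select(target, clause_id, clause, size, literals)
}
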