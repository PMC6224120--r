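#' Boolean networks in disjunctive normal form
#'
#' A Boolean network assigns each node a regulatory function, written as a
#' disjunction of conjunctive clauses over signed literals (the hyper-edges).
#' A node with no clauses keeps its current value (identity function), which
#' is how unregulated source nodes are frozen at their initial value.
#'
#' @param nodes Character vector of node names (defines state vector order).
#' @param functions Named list (names in `nodes`): each element is a list of
#'   clauses, a clause being a named integer vector of +1/-1 over regulator
#'   names. Nodes absent from `functions` (or mapped to an empty list) get the
#'   identity function. Duplicate clauses within a node are an error.
#' @return An object of class `boolean_network`.
#' @examples
#' bn <- boolean_network(
#'   nodes = c("s", "r"),
#'   functions = list(r = list(c(s = 1)))
#' )
#' tidy(bn)
#' @export
boolean_network <- function(nodes, functions = list()) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  unknown <- setdiff(names(functions), nodes)
  if (length(unknown) > 0L) {
    stop("functions for undeclared node(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  fns <- setNames(vector("list", length(nodes)), nodes)
  for (nd in names(functions)) {
    cls <- functions[[nd]]
    if (length(cls) == 0L) next
    cls <- lapply(cls, canonical_clause)
    for (cl in cls) {
      bad <- setdiff(names(cl), nodes)
      if (length(bad) > 0L) {
        stop("clause regulator(s) not declared as nodes: ",
          paste(bad, collapse = ", "),
          call. = FALSE
        )
      }
    }
    printed <- vapply(cls, format_clause, character(1))
    if (anyDuplicated(printed)) {
      stop("duplicate hyper-edge on node ", nd, call. = FALSE)
    }
    fns[[nd]] <- cls[order(lengths(cls), printed)]
  }
  structure(list(nodes = nodes, functions = fns), class = "boolean_network")
}

canonical_clause <- function(cl) {
  if (length(cl) == 0L) stop("empty clause", call. = FALSE)
  if (is.null(names(cl)) || any(names(cl) == "")) {
    stop("clause literals must be named by regulator", call. = FALSE)
  }
  if (anyDuplicated(names(cl))) {
    stop("clause contains one regulator twice", call. = FALSE)
  }
  if (!all(cl %in% c(-1L, 1L))) stop("literal polarity must be +1 or -1", call. = FALSE)
  cl <- setNames(as.integer(cl), names(cl))
  cl[order(names(cl))]
}

format_clause <- function(cl) {
  cl <- canonical_clause(cl)
  paste0(ifelse(cl < 0L, "!", ""), names(cl), collapse = "&")
}

parse_clause <- function(s) {
  lits <- strsplit(trimws(s), "&", fixed = TRUE)[[1]]
  lits <- trimws(lits)
  if (length(lits) == 0L || any(lits == "")) stop("cannot parse clause: ", s, call. = FALSE)
  neg <- startsWith(lits, "!")
  regs <- sub("^!", "", lits)
  canonical_clause(setNames(ifelse(neg, -1L, 1L), regs))
}

#' @export
print.boolean_network <- function(x, ...) {
  he <- bn_hyperedges(x)
  cat(sprintf("<boolean_network> %d nodes, %d hyper-edges\n", length(x$nodes), nrow(he)))
  if (nrow(he) > 0L) {
    cat(paste0("  ", he$target, " <- ", he$clause, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Hyper-edges of a Boolean network
#'
#' One row per clause of each node's regulatory function; `hyperedge` is the
#' canonical `"target <- clause"` string used throughout family analytics.
#'
#' @param bn A `boolean_network`.
#' @return Tibble with columns `target`, `clause`, `hyperedge`.
#' @export
bn_hyperedges <- function(bn) {
  stopifnot(inherits(bn, "boolean_network"))
  rows <- imap(bn$functions, function(cls, nd) {
    if (length(cls) == 0L) return(NULL)
    tibble(target = nd, clause = vapply(cls, format_clause, character(1)))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble(target = character(), clause = character(), hyperedge = character()))
  }
  out %>%
    mutate(hyperedge = paste(target, "<-", clause)) %>%
    arrange(target, clause)
}

hyperedge_set <- function(bn) bn_hyperedges(bn)$hyperedge

#' Read / write Boolean networks as hyper-edge text
#'
#' One line per hyper-edge, `target <- lit&lit`, with `!` marking negation;
#' repeated target lines form the disjunction. Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @param nodes Optional full node universe; defaults to the nodes mentioned
#'   in the file (regulators and targets).
#' @return `read_bn`: a `boolean_network`. `write_bn`: `path`, invisibly.
#' @export
read_bn <- function(path, nodes = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "<-", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed hyper-edge line in ", path, call. = FALSE)
  targets <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  clauses <- lapply(parts, function(p) parse_clause(p[[2]]))
  mentioned <- unique(c(targets, unlist(lapply(clauses, names))))
  if (is.null(nodes)) nodes <- mentioned
  fns <- split(clauses, targets)
  boolean_network(nodes, fns)
}

#' @rdname read_bn
#' @param bn A `boolean_network`.
#' @export
write_bn <- function(bn, path) {
  he <- bn_hyperedges(bn)
  writeLines(c(
    paste0("# nodes: ", paste(bn$nodes, collapse = " ")),
    paste(he$target, "<-", he$clause)
  ), path)
  invisible(path)
}
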