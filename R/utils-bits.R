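# Bit-level helpers for explicit-state work. States over n <= 30 nodes are packed
# into a single R integer; node i (1-based, in the network's node order) occupies
# bit i-1. All masks are non-negative integers, so bitwNot() is avoided in favour
# of XOR with the full mask.

MAX_PACKED_NODES <- 30L

bit_masks <- function(n) {
  stopifnot(n >= 1L, n <= MAX_PACKED_NODES)
  as.integer(2^(seq_len(n) - 1L))
}

full_mask <- function(n) {
  if (n >= 31L) stop("state packing supports at most 30 nodes", call. = FALSE)
  as.integer(2^n - 1)
}

# All non-zero submasks of `mask`, in the standard descending enumeration.
submasks <- function(mask) {
  if (mask == 0L) return(integer(0))
  out <- integer(0)
  s <- mask
  repeat {
    out <- c(out, s)
    s <- bitwAnd(s - 1L, mask)
    if (s == 0L) break
  }
  out
}

popcount <- function(x) {
  n <- 0L
  while (x != 0L) {
    x <- bitwAnd(x, x - 1L)
    n <- n + 1L
  }
  n
}

# Pack a named 0/1 vector (possibly partial) into (mask, value) integers given
# the node order. Returns list(mask=, value=).
pack_partial <- function(values, nodes) {
  if (length(values) == 0L) return(list(mask = 0L, value = 0L))
  if (is.null(names(values))) stop("state vectors must be named by node", call. = FALSE)
  unknown <- setdiff(names(values), nodes)
  if (length(unknown) > 0L) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (!all(values %in% c(0, 1))) stop("state values must be 0 or 1", call. = FALSE)
  bits <- bit_masks(length(nodes))
  idx <- match(names(values), nodes)
  mask <- sum(bits[idx])
  value <- sum(bits[idx][values == 1])
  list(mask = as.integer(mask), value = as.integer(value))
}

pack_state <- function(x, nodes) {
  if (length(x) != length(nodes)) {
    stop("state must assign every node exactly once", call. = FALSE)
  }
  if (!is.null(names(x))) x <- x[nodes]
  if (anyNA(x)) stop("state is missing a value for some node", call. = FALSE)
  p <- pack_partial(setNames(as.integer(x), nodes), nodes)
  p$value
}

unpack_state <- function(s, nodes) {
  bits <- bit_masks(length(nodes))
  setNames(as.integer(bitwAnd(s, bits) != 0L), nodes)
}
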