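# Full state space: the tree of all action prefixes. States are numbered
# breadth-first from the root s1, so depth-i states (i residues placed) occupy
# the index block ( (b^(i-1)-1)/(b-1), (b^i-1)/(b-1) ].

# Largest double that is still an exact integer.
.MAX_EXACT <- 2^53

# -- minimal exact integer arithmetic on base-1e7 digit vectors -------------
# (little-endian); enough for (b^n - 1)/(b - 1) at n <= 64 without external
# big-integer libraries.
.big_from_int <- function(x) as.numeric(x)
.big_mul_small <- function(d, m) {
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] * m + carry
    d[i] <- v %% 1e7
    carry <- v %/% 1e7
  }
  while (carry > 0) {
    d <- c(d, carry %% 1e7)
    carry <- carry %/% 1e7
  }
  d
}
.big_add_small <- function(d, a) {
  i <- 1L
  carry <- a
  while (carry > 0) {
    if (i > length(d)) d <- c(d, 0)
    v <- d[i] + carry
    d[i] <- v %% 1e7
    carry <- v %/% 1e7
    i <- i + 1L
  }
  d
}
.big_to_string <- function(d) {
  s <- paste0(sprintf("%07.0f", rev(d[-length(d)])), collapse = "")
  paste0(sprintf("%.0f", d[length(d)]), s)
}

#' Size of the full state space
#'
#' The full state space for a chain of `n` residues with branching `b` (4 for
#' the L/U/R/D action set, 3 for the reduced set) is a perfect b-ary tree of
#' depth n: one state per action prefix, `(b^n - 1)/(b - 1)` in total (the
#' geometric series 1 + b + b^2 + ... + b^(n-1)).
#'
#' Computed in exact integer arithmetic for any `n <= 64`; the result is
#' returned as a numeric when exactly representable as a double, otherwise as
#' a decimal character string.
#'
#' @param n Chain length (>= 1).
#' @param b Branching factor, 3 or 4.
#' @return Exact state count (numeric, or character for very large n).
#' @examples
#' full_state_count(2, 4)  # 5
#' full_state_count(3, 4)  # 21
#' @export
full_state_count <- function(n, b = 4) {
  stopifnot(length(n) == 1L, n >= 1, n == floor(n))
  if (!b %in% c(3, 4)) stop("branching `b` must be 3 or 4", call. = FALSE)
  if (n > 64) stop("n must be <= 64", call. = FALSE)
  # Horner form of 1 + b + ... + b^(n-1) on exact digit vectors
  d <- .big_from_int(1)
  for (i in seq_len(n - 1)) d <- .big_add_small(.big_mul_small(d, b), 1)
  val <- sum(d * 1e7^(seq_along(d) - 1))
  if (val < .MAX_EXACT) val else .big_to_string(d)
}

# offset(i) = number of states at depth < i+1, i.e. (b^i - 1)/(b - 1);
# exact in doubles while b^i < 2^53.
.depth_offset <- function(i, b) (b^i - 1) / (b - 1)

#' Depth and ordinal of a state index
#'
#' Inverts the breadth-first numbering: state `s` lies at depth `i` (the index
#' of the residue it places) with ordinal `k` in `[1, b^(i-1)]`, and
#' `s = (b^(i-1) - 1)/(b - 1) + k`. The mapping is bijective.
#'
#' @param s State index (1-based; `s = 1` is the root).
#' @param b Branching factor, 3 or 4.
#' @return List with integers `depth` and `ordinal`.
#' @export
state_address <- function(s, b = 4) {
  check_state_index(s, b)
  i <- 1L
  while (.depth_offset(i, b) < s) i <- i + 1L
  list(depth = i, ordinal = s - .depth_offset(i - 1L, b))
}

check_state_index <- function(s, b) {
  if (!b %in% c(3, 4)) stop("branching `b` must be 3 or 4", call. = FALSE)
  if (length(s) != 1L || is.na(s) || s < 1 || s != floor(s)) {
    stop("state index must be a positive integer", call. = FALSE)
  }
  if (s >= .MAX_EXACT) stop("state index exceeds exact double range (2^53)", call. = FALSE)
  invisible(s)
}

#' State transition in the full state space
#'
#' Taking action `l` in the depth-i, ordinal-k state moves to the depth-(i+1)
#' state with index `(b^i - 1)/(b - 1) + b*(k - 1) + l`: each state has `b`
#' children, distinct (state, action) pairs have distinct successors, and the
#' depth always increases by exactly one.
#'
#' @param s Current state index.
#' @param l Action number in `1..b`.
#' @param b Branching factor, 3 or 4.
#' @param n Optional chain length; when given, transitions out of a depth-n
#'   (terminal) state are rejected.
#' @return Successor state index.
#' @examples
#' transfer(1, 1, b = 4)  # s2
#' transfer(2, 1, b = 4)  # s6, first state of depth 3
#' @export
transfer <- function(s, l, b = 4, n = NULL) {
  addr <- state_address(s, b)
  if (length(l) != 1L || is.na(l) || l < 1 || l > b || l != floor(l)) {
    stop("action `l` must lie in 1..", b, call. = FALSE)
  }
  if (!is.null(n) && addr$depth >= n) {
    stop("cannot transfer from a terminal (depth-n) state", call. = FALSE)
  }
  out <- .depth_offset(addr$depth, b) + b * (addr$ordinal - 1) + l
  check_state_index(out, b)
}

#' Decode a state index into its action prefix
#'
#' Every state corresponds to a unique action history from the root; this
#' returns that prefix (empty for s1) by repeatedly inverting the transition
#' formula.
#'
#' @inheritParams state_address
#' @return Integer vector of actions in `1..b` (length = depth - 1).
#' @export
state_to_prefix <- function(s, b = 4) {
  addr <- state_address(s, b)
  k <- addr$ordinal - 1  # 0-based ordinal is the prefix read as a base-b numeral
  acts <- integer(addr$depth - 1L)
  for (pos in rev(seq_len(addr$depth - 1L))) {
    acts[pos] <- k %% b + 1
    k <- k %/% b
  }
  as.integer(acts)
}

#' Encode an action prefix as a state index
#'
#' Inverse of [state_to_prefix()]: folds [transfer()] from the root.
#'
#' @param prefix Integer vector of actions in `1..b` (possibly empty).
#' @param b Branching factor, 3 or 4.
#' @return State index.
#' @export
prefix_to_state <- function(prefix, b = 4) {
  s <- 1
  for (l in prefix) s <- transfer(s, l, b)
  s
}

#' Partial-state index
#'
#' The partial state space compresses the full tree to `1 + 4(n - 1)` states:
#' the root plus one state per (residue index, last absolute action) pair.
#' Distinct histories alias to the same state, so the process loses the
#' Markov property.
#'
#' @param i Residue index in `1..n`.
#' @param l Last action in `1..4` (ignored for `i = 1`).
#' @return State index: 1 for `i = 1`, else `1 + 4(i - 2) + l`.
#' @examples
#' partial_state_of(2, 1)  # 2
#' partial_state_of(3, 4)  # 9
#' @export
partial_state_of <- function(i, l = NULL) {
  stopifnot(length(i) == 1L, i >= 1, i == floor(i))
  if (i == 1) return(1)
  if (is.null(l)) stop("last action `l` is required for i >= 2", call. = FALSE)
  stopifnot(l >= 1, l <= 4, l == floor(l))
  1 + 4 * (i - 2) + l
}

#' Number of partial states
#'
#' @param n Chain length.
#' @return `1 + 4(n - 1)`.
#' @export
partial_state_count <- function(n) {
  stopifnot(n >= 1)
  1 + 4 * (n - 1)
}
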