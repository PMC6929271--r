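#' Exact ground-state energy by pruned self-avoiding-walk enumeration
#'
#' Depth-first search over all self-avoiding walks of the chain from the
#' origin, returning the exact minimum of the HP contact energy over legal
#' conformations. Two accelerations, both optional and both verified against
#' the unaccelerated search:
#' \describe{
#'   \item{symmetry_reduce}{fixes the first step to +x and the first turn (if
#'     any) to +y, enumerating exactly one representative per class of the 8
#'     lattice point symmetries.}
#'   \item{bound_prune}{branch-and-bound cut using an admissible bound on the
#'     remaining contacts: each unplaced H residue can gain at most 2 further
#'     contacts (3 for the chain end), since a chain residue has at most that
#'     many free non-bond neighbours.}
#' }
#'
#' `optimum_count` is reported under the enumeration's symmetry convention:
#' with `symmetry_reduce = TRUE` it counts symmetry *classes* of optimal
#' walks, not the (up to 8x larger) number of congruent placements.
#'
#' @param seq An [hp_sequence()] or H/P string.
#' @param symmetry_reduce Use the 8-fold symmetry reduction.
#' @param bound_prune Use branch-and-bound pruning.
#' @param node_cap Abort (with `truncated = TRUE`) after exploring this many
#'   nodes; `Inf` disables the cap. A truncated result is flagged, never
#'   silently wrong.
#' @param restrict Restrict the search to an encoding-reachable subset:
#'   `"none"` (all self-avoiding walks) or `"absolute3"` (walks that never
#'   step in -y — the partially directed walks expressible with absolute
#'   L/U/R actions; forces `symmetry_reduce = FALSE` since that subset is not
#'   closed under the lattice symmetries).
#' @return List of class `hp_enum_result`: `min_energy`, `optimum_count`,
#'   `explored`, `truncated`.
#' @examples
#' enumerate_min_energy("HPPH")$min_energy      # -1
#' enumerate_min_energy("HPPHHPH")$min_energy   # -2
#' @export
enumerate_min_energy <- function(seq, symmetry_reduce = TRUE,
                                 bound_prune = TRUE, node_cap = Inf,
                                 restrict = c("none", "absolute3")) {
  seq <- hp_sequence(seq)
  restrict <- match.arg(restrict)
  if (restrict == "absolute3") symmetry_reduce <- FALSE
  isH <- as.integer(hp_residues(seq) == "H")
  cap <- if (is.infinite(node_cap)) 0 else as.double(node_cap)
  res <- cpp_enumerate(isH, symmetry_reduce, bound_prune, cap,
                       if (restrict == "absolute3") 3L else -1L)
  structure(res, class = "hp_enum_result")
}

#' @export
print.hp_enum_result <- function(x, ...) {
  cat("<hp_enum_result> min energy:", x$min_energy,
      "| optima:", x$optimum_count,
      "| nodes:", format(x$explored, big.mark = ","),
      if (x$truncated) "| TRUNCATED" else "", "\n")
  invisible(x)
}

#' Naive exhaustive enumeration (secondary oracle)
#'
#' Enumerates every one of the `4^(n-1)` absolute move strings, keeps the
#' legal (self-avoiding) walks and minimizes the energy — no pruning, no
#' symmetry reduction. Deliberately independent of the fast enumerator (pure
#' R, pairwise energy via [energy()]); used to cross-validate it at small n.
#'
#' @param seq An [hp_sequence()] with at most 9 residues.
#' @param keep_optima Also return the optimal conformations.
#' @return List of class `hp_enum_result`: `min_energy`, `optimum_count`
#'   (count over *all* legal walks, no symmetry convention), `explored`
#'   (strings tried), `truncated = FALSE`, and optionally `optima`.
#' @export
naive_enumerate <- function(seq, keep_optima = FALSE) {
  seq <- hp_sequence(seq)
  n <- length(seq)
  if (n > 9) stop("naive enumeration is restricted to n <= 9 (4^(n-1) walks)",
                  call. = FALSE)
  if (n == 1) {
    return(structure(list(min_energy = 0L, optimum_count = 1,
                          explored = 1, truncated = FALSE),
                     class = "hp_enum_result"))
  }
  grid <- as.matrix(expand.grid(rep(list(1:4), n - 1L)))
  emin <- 0L
  optima <- list()
  count <- 0
  for (r in seq_len(nrow(grid))) {
    conf <- decode_moves(grid[r, ], "absolute4")
    if (!is_legal(conf)) next
    e <- energy(seq, conf)
    if (e < emin) {
      emin <- e; count <- 1; optima <- list(conf)
    } else if (e == emin) {
      count <- count + 1
      if (keep_optima) optima <- c(optima, list(conf))
    }
  }
  out <- list(min_energy = emin, optimum_count = count,
              explored = nrow(grid), truncated = FALSE)
  if (keep_optima) out$optima <- optima
  structure(out, class = "hp_enum_result")
}
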