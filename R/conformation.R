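# Lattice geometry. Directions are numbered 0:3 = +x, +y, -x, -y; absolute
# actions follow the convention a1 = L, a2 = U, a3 = R, a4 = D.

.DIR_DX <- c(1L, 0L, -1L, 0L)
.DIR_DY <- c(0L, 1L, 0L, -1L)
.ABS4_DIR <- c(L = 2L, U = 1L, R = 0L, D = 3L)  # action index 1..4 -> direction 0..3
.ABS4_TO_DIR <- c(2L, 1L, 0L, 3L)
.ABS3_TO_DIR <- c(2L, 1L, 0L)                   # a1=L, a2=U, a3=R (no -y step)
.REL3_TURN <- c(1L, 0L, 3L)                     # a1=turn left, a2=straight, a3=turn right

#' Construct a conformation from lattice coordinates
#'
#' A conformation is the ordered list of integer lattice positions of the
#' residues of a chain. It is a *chain* when consecutive residues sit at unit
#' (Manhattan) distance, and *legal* when additionally no two residues share a
#' cell — i.e. when the coordinates trace a self-avoiding walk.
#'
#' @param coords Integer matrix with n rows and columns x, y.
#' @return Object of class `hp_conformation`: a list with elements `coords`
#'   (n x 2 integer matrix) and `legal` (logical).
#' @export
hp_conformation <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  if (ncol(coords) != 2L || nrow(coords) < 1L || anyNA(coords)) {
    stop("`coords` must be an n x 2 integer matrix without NAs", call. = FALSE)
  }
  colnames(coords) <- c("x", "y")
  n <- nrow(coords)
  chain_ok <- n == 1L ||
    all(abs(diff(coords[, 1])) + abs(diff(coords[, 2])) == 1L)
  if (!chain_ok) {
    stop("consecutive residues must be at unit lattice distance", call. = FALSE)
  }
  structure(list(coords = coords, legal = !anyDuplicated(coords)),
            class = "hp_conformation")
}

#' @export
print.hp_conformation <- function(x, ...) {
  cat("<hp_conformation> n =", nrow(x$coords),
      if (x$legal) "(legal)" else "(ILLEGAL: overlap)", "\n")
  print(utils::head(as.data.frame(x$coords), 10))
  if (nrow(x$coords) > 10) cat("  ...\n")
  invisible(x)
}

#' Decode a move string into a conformation
#'
#' Residue 1 is fixed at the origin; each move appends one unit step. Three
#' encodings are supported:
#' \describe{
#'   \item{absolute4}{actions 1..4 = L, U, R, D, fixed lattice directions.}
#'   \item{absolute3}{actions 1..3 = L, U, R; the chain can never step in -y,
#'     restricting it to partially directed walks.}
#'   \item{relative3}{actions 1..3 = turn-left, straight, turn-right with
#'     respect to the previous bond; the first bond's reference direction is
#'     +x. This encoding reaches every self-avoiding conformation up to
#'     lattice symmetry.}
#' }
#'
#' @param moves Integer vector of action numbers, or a single string of action
#'   letters ("LURD" for absolute encodings, "LSR" for relative3).
#' @param encoding One of "absolute4", "absolute3", "relative3".
#' @return An [hp_conformation()] with `legal` reflecting self-avoidance.
#' @examples
#' decode_moves("RRR", "absolute4")   # straight line, legal
#' decode_moves("RL", "absolute4")    # immediate backtrack, illegal
#' @export
decode_moves <- function(moves, encoding = c("relative3", "absolute3", "absolute4")) {
  encoding <- match.arg(encoding)
  moves <- parse_moves(moves, encoding)
  hp_conformation(moves_to_coords(moves, encoding))
}

parse_moves <- function(moves, encoding) {
  b <- if (encoding == "absolute4") 4L else 3L
  if (is.character(moves) && length(moves) == 1L) {
    letters_for <- if (encoding == "relative3") c("L", "S", "R") else c("L", "U", "R", "D")[seq_len(b)]
    sym <- strsplit(toupper(moves), "")[[1]]
    idx <- match(sym, letters_for)
    if (anyNA(idx)) {
      stop("invalid move symbol(s) for encoding ", encoding, ": ",
           paste(unique(sym[is.na(idx)]), collapse = ", "), call. = FALSE)
    }
    moves <- idx
  }
  moves <- as.integer(moves)
  if (any(moves < 1L | moves > b)) {
    stop("action numbers must lie in 1..", b, " for encoding ", encoding, call. = FALSE)
  }
  moves
}

moves_to_coords <- function(moves, encoding) {
  n <- length(moves) + 1L
  x <- integer(n); y <- integer(n)
  if (encoding == "relative3") {
    dir <- 0L
    for (i in seq_along(moves)) {
      dir <- (dir + .REL3_TURN[moves[i]]) %% 4L
      x[i + 1L] <- x[i] + .DIR_DX[dir + 1L]
      y[i + 1L] <- y[i] + .DIR_DY[dir + 1L]
    }
  } else {
    map <- if (encoding == "absolute4") .ABS4_TO_DIR else .ABS3_TO_DIR
    dir <- map[moves]
    x <- c(0L, cumsum(.DIR_DX[dir + 1L]))
    y <- c(0L, cumsum(.DIR_DY[dir + 1L]))
  }
  cbind(x = x, y = y)
}

#' Re-encode a conformation as a move string
#'
#' Inverse of [decode_moves()]. For `relative3` the first bond must point in
#' +x (the reference direction); rotate the conformation first if needed.
#'
#' @param conf An [hp_conformation()].
#' @inheritParams decode_moves
#' @param as_string Return a compact letter string instead of action numbers.
#' @return Integer action vector, or a string when `as_string = TRUE`.
#' @export
encode_moves <- function(conf, encoding = c("relative3", "absolute3", "absolute4"),
                         as_string = FALSE) {
  encoding <- match.arg(encoding)
  xy <- conf$coords
  dx <- diff(xy[, 1]); dy <- diff(xy[, 2])
  dir <- match(paste(dx, dy), paste(.DIR_DX, .DIR_DY)) - 1L
  if (anyNA(dir)) stop("conformation is not a unit-step chain", call. = FALSE)
  if (encoding == "relative3") {
    prev <- c(0L, dir[-length(dir)])
    turn <- (dir - prev) %% 4L
    acts <- match(turn, .REL3_TURN)
    if (anyNA(acts)) stop("chain reverses direction; not encodable in relative3", call. = FALSE)
    letters_for <- c("L", "S", "R")
  } else {
    map <- if (encoding == "absolute4") .ABS4_TO_DIR else .ABS3_TO_DIR
    acts <- match(dir, map)
    if (anyNA(acts)) stop("conformation uses a direction outside encoding ", encoding, call. = FALSE)
    letters_for <- c("L", "U", "R", "D")
  }
  if (as_string) paste(letters_for[acts], collapse = "") else acts
}

#' Test the three legality constraints
#'
#' A legitimate configuration must (1) sit on integer 2D coordinates, (2) have
#' consecutive residues at unit distance, and (3) occupy pairwise-distinct
#' cells. Constraints (1)-(2) are enforced at construction; this predicate
#' reports whether all three hold.
#'
#' @param conf An [hp_conformation()].
#' @return `TRUE` iff the conformation is a self-avoiding walk.
#' @export
is_legal <- function(conf) {
  stopifnot(inherits(conf, "hp_conformation"))
  isTRUE(conf$legal)
}

#' Hydrophobic topological contacts of a conformation
#'
#' A topological contact is a pair of H residues that are not adjacent in the
#' sequence (|i - j| >= 2) but occupy lattice cells at unit distance. Each
#' contact contributes -1 to the energy. The pair list is computed
#' mechanically from coordinates, so it is defined even for overlapping
#' (illegal) conformations.
#'
#' @param seq An [hp_sequence()].
#' @param conf An [hp_conformation()] with one coordinate per residue.
#' @return Data frame with columns `i`, `j` (1-based, `j > i + 1`).
#' @export
contacts <- function(seq, conf) {
  seq <- hp_sequence(seq)
  xy <- conf$coords
  if (nrow(xy) != length(seq)) {
    stop("sequence has ", length(seq), " residues but conformation has ",
         nrow(xy), call. = FALSE)
  }
  h <- which(hp_residues(seq) == "H")
  out <- data.frame(i = integer(), j = integer())
  if (length(h) >= 2) {
    pr <- utils::combn(h, 2)
    i <- pr[1, ]; j <- pr[2, ]
    keep <- (j - i >= 2L) &
      (abs(xy[i, 1] - xy[j, 1]) + abs(xy[i, 2] - xy[j, 2]) == 1L)
    out <- data.frame(i = i[keep], j = j[keep])
  }
  out[order(out$i, out$j), , drop = FALSE]
}

#' HP contact energy of a conformation
#'
#' The energy is the number of hydrophobic topological contacts, each counted
#' as -1: `E = sum_{i<j} W_ij` with `W_ij = -1` when residues i and j are both
#' H, non-adjacent in sequence, and adjacent on the lattice, else 0. Always
#' <= 0. Defined for illegal conformations too (pairs at unit distance count
#' mechanically), which the flexible training criterion relies on.
#'
#' @inheritParams contacts
#' @return Integer energy (<= 0).
#' @examples
#' energy("HPPH", decode_moves("RUL", "absolute4"))  # U-fold, one contact: -1
#' @export
energy <- function(seq, conf) {
  -nrow(contacts(seq, conf))
}

#' Occupancy (check) grid of a conformation
#'
#' Builds the (2n-1) x (2n-1) boolean check matrix used by the rigid
#' criterion: residue 1 sits at the grid centre, so no chain of n-1 unit steps
#' can leave the grid. A cell is `TRUE` iff some placed residue occupies it.
#'
#' @param conf An [hp_conformation()].
#' @param n Chain length the grid is sized for (defaults to the number of
#'   placed residues; pass the full length when the conformation is partial).
#' @return Logical (2n-1) x (2n-1) matrix; attribute `origin` gives the
#'   row/column index (n, n) of lattice coordinate (0, 0).
#' @export
occupancy_grid <- function(conf, n = nrow(conf$coords)) {
  xy <- conf$coords
  if (any(abs(xy) > n - 1L)) stop("coordinates exceed the (2n-1)^2 grid", call. = FALSE)
  g <- matrix(FALSE, 2L * n - 1L, 2L * n - 1L)
  g[cbind(xy[, 1] + n, xy[, 2] + n)] <- TRUE
  attr(g, "origin") <- c(n, n)
  g
}

#' Apply a lattice symmetry to a conformation
#'
#' The square lattice has 8 point symmetries (4 rotations x optional
#' reflection). Energy and legality are invariant under all of them and under
#' translation.
#'
#' @param conf An [hp_conformation()].
#' @param rot Number of counter-clockwise quarter turns (0-3).
#' @param reflect Reflect across the x axis (applied before rotation).
#' @return Transformed [hp_conformation()].
#' @export
transform_conformation <- function(conf, rot = 0L, reflect = FALSE) {
  xy <- conf$coords
  if (reflect) xy[, 2] <- -xy[, 2]
  for (k in seq_len(rot %% 4L)) xy <- cbind(x = -xy[, 2], y = xy[, 1])
  colnames(xy) <- c("x", "y")
  hp_conformation(xy)
}

#' Canonical key of a conformation
#'
#' Representative of a conformation's equivalence class under translation
#' and, optionally, the 8 lattice point symmetries: the lexicographically
#' smallest coordinate string over all images re-anchored at residue 1. Two
#' conformations are congruent iff their keys match.
#'
#' @param conf An [hp_conformation()].
#' @param symmetries Quotient by the 8 point symmetries too (else only by
#'   translation).
#' @return Character key.
#' @export
canonical_form <- function(conf, symmetries = TRUE) {
  imgs <- if (symmetries) {
    unlist(lapply(c(FALSE, TRUE), function(rf)
      lapply(0:3, function(r) transform_conformation(conf, r, rf))),
      recursive = FALSE)
  } else list(conf)
  keys <- vapply(imgs, function(cf) {
    xy <- sweep(cf$coords, 2, cf$coords[1, ])
    paste(t(xy), collapse = ",")
  }, character(1))
  min(keys)
}

#' Write a conformation as TSV
#'
#' Emits one row per residue with columns `index`, `residue`, `x`, `y`.
#'
#' @inheritParams contacts
#' @param path Output file; `""` writes to stdout.
#' @return The data frame, invisibly.
#' @export
write_conformation <- function(seq, conf, path = "") {
  seq <- hp_sequence(seq)
  df <- data.frame(index = seq_len(nrow(conf$coords)),
                   residue = hp_residues(seq),
                   x = conf$coords[, 1], y = conf$coords[, 2])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Text rendering of a folded chain
#'
#' Convenience ASCII plot: H residues as `H`, P as `p`, residue 1 as `1`/`h`.
#'
#' @inheritParams contacts
#' @return Character vector of lines, invisibly; printed as a side effect.
#' @export
draw_conformation <- function(seq, conf) {
  seq <- hp_sequence(seq)
  xy <- conf$coords
  res <- hp_residues(seq)
  xs <- range(xy[, 1]); ys <- range(xy[, 2])
  grid <- matrix(".", ys[2] - ys[1] + 1L, xs[2] - xs[1] + 1L)
  for (i in seq_len(nrow(xy))) {
    r <- ys[2] - xy[i, 2] + 1L
    c <- xy[i, 1] - xs[1] + 1L
    ch <- if (res[i] == "H") "H" else "p"
    if (i == 1L) ch <- if (res[i] == "H") "h" else "o"
    grid[r, c] <- ch
  }
  lines <- apply(grid, 1, paste, collapse = " ")
  cat(lines, sep = "\n")
  invisible(lines)
}
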