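#' Construct a validated HP sequence
#'
#' An HP sequence is the problem instance of the 2D hydrophobic-polar lattice
#' model: an ordered string over the two-letter alphabet \{H, P\}, where H
#' marks a hydrophobic residue and P a polar (hydrophilic) one. Input is
#' upper-cased before validation.
#'
#' @param x A single character string over \{H, P\} (case-insensitive), or an
#'   existing `hp_sequence`.
#' @return An object of class `hp_sequence`: the validated string, with the
#'   residue count available through [length()].
#' @examples
#' s <- hp_sequence("HPPHHPH")
#' length(s)
#' @export
hp_sequence <- function(x) {
  if (inherits(x, "hp_sequence")) return(x)
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("`x` must be a single character string over {H, P}", call. = FALSE)
  }
  x <- toupper(gsub("[[:space:]]", "", x))
  if (nchar(x) < 1L) stop("an HP sequence needs at least one residue", call. = FALSE)
  if (grepl("[^HP]", x)) {
    bad <- unique(strsplit(gsub("[HP]", "", x), "")[[1]])
    stop("invalid residue symbol(s): ", paste(bad, collapse = ", "),
         " (only H and P are allowed)", call. = FALSE)
  }
  structure(x, class = "hp_sequence")
}

#' @export
length.hp_sequence <- function(x) nchar(unclass(x))

#' @export
print.hp_sequence <- function(x, ...) {
  cat("<hp_sequence> n =", length(x), "\n ", unclass(x), "\n")
  invisible(x)
}

#' @export
as.character.hp_sequence <- function(x, ...) unclass(x)

#' Residue symbols of an HP sequence
#'
#' @param seq An [hp_sequence()] (or coercible string).
#' @return Character vector of "H"/"P", one element per residue.
#' @export
hp_residues <- function(seq) {
  strsplit(as.character(hp_sequence(seq)), "")[[1]]
}

#' Map an amino-acid sequence to an HP sequence
#'
#' Collapses a 20-letter amino-acid string to the two-letter HP alphabet. The
#' set of residues treated as hydrophobic is a modelling choice and must suit
#' the study at hand; the default follows the common convention of classing
#' the apolar residues A, C, F, I, L, M, V, W, Y as hydrophobic and everything
#' else as polar. Pass your own `hydrophobic` set to override.
#'
#' @param x Single amino-acid string (one-letter codes).
#' @param hydrophobic Character vector of one-letter codes to map to H.
#' @return An [hp_sequence()].
#' @export
aa_to_hp <- function(x, hydrophobic = c("A", "C", "F", "I", "L", "M", "V", "W", "Y")) {
  stopifnot(is.character(x), length(x) == 1L)
  res <- strsplit(toupper(gsub("[[:space:]]", "", x)), "")[[1]]
  hydrophobic <- toupper(hydrophobic)
  hp_sequence(paste(ifelse(res %in% hydrophobic, "H", "P"), collapse = ""))
}

#' Read HP sequences from a file
#'
#' Accepts either a plain-text list (one H/P string per line, blank lines and
#' `#` comments ignored) or a FASTA file whose sequence lines are restricted to
#' H/P (detected by a leading `>`; parsed with the seqinr package).
#'
#' @param path File path.
#' @return Named list of [hp_sequence()] objects (plain-text entries are named
#'   seq1, seq2, ... unless the line carries a `name:` prefix).
#' @export
read_hp_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  first <- lines[nzchar(trimws(lines))]
  if (length(first) && startsWith(trimws(first[1]), ">")) {
    if (!requireNamespace("seqinr", quietly = TRUE)) {
      stop("reading FASTA input requires the seqinr package", call. = FALSE)
    }
    recs <- seqinr::read.fasta(path, as.string = TRUE, seqtype = "AA")
    out <- lapply(recs, function(r) hp_sequence(as.character(r)))
    names(out) <- names(recs)
    return(out)
  }
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  nm <- sprintf("seq%d", seq_along(lines))
  has_name <- grepl(":", lines, fixed = TRUE)
  nm[has_name] <- trimws(sub(":.*$", "", lines[has_name]))
  lines[has_name] <- trimws(sub("^[^:]*:", "", lines[has_name]))
  out <- lapply(lines, hp_sequence)
  names(out) <- nm
  out
}
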