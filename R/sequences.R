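# Sequence-level primitives for PNA homoduplexes.
#
# PNA strands are written N-terminus -> C-terminus over the four canonical
# bases. The duplex partner is always implied by antiparallel Watson-Crick
# complementarity and never stored.

#' Canonical nearest-neighbor stack classes
#'
#' The 16 dinucleotides of a homoduplex collapse into 10 symmetry-unique
#' stack classes under the antiparallel-duplex equivalence
#' `X1X2 == comp(X2)comp(X1)`. Each class carries the number of canonical
#' Watson-Crick hydrogen bonds shared by its two base pairs: 6 for GG, GC
#' and CG; 5 for AG, GA, AC and CA; 4 for AA, AT and TA.
#'
#' @return A tibble with columns `stack` (the 10 canonical labels, in the
#'   fixed column order used throughout the package) and `wc_hbonds`.
#' @export
#' @examples
#' stack_classes()
stack_classes <- function() {
  tibble::tibble(
    stack = c("AA", "AT", "TA", "AG", "GA", "AC", "CA", "GG", "GC", "CG"),
    wc_hbonds = c(4L, 4L, 4L, 5L, 5L, 5L, 5L, 6L, 6L, 6L)
  )
}

# Fixed column order for design matrices and parameter sets.
.stack_order <- c("AA", "AT", "TA", "AG", "GA", "AC", "CA", "GG", "GC", "CG")
.term_order <- c(.stack_order, "Init", "T.GC")

.base_complement <- c(A = "T", T = "A", G = "C", C = "G")

#' Validate a PNA sequence
#'
#' Uppercases, strips surrounding whitespace, and checks that the result is
#' a string of length >= 2 over the alphabet A/C/G/T. Offending characters
#' are reported with their position.
#'
#' @param raw Character vector of raw sequence strings (N -> C).
#' @return The validated, uppercased character vector.
#' @export
#' @examples
#' validate_sequence("cgatcg")
validate_sequence <- function(raw) {
  if (length(raw) == 0 || !is.character(raw)) {
    stop("`raw` must be a non-empty character vector", call. = FALSE)
  }
  out <- toupper(trimws(raw))
  for (k in seq_along(out)) {
    s <- out[[k]]
    if (is.na(s) || nchar(s) < 2) {
      stop("sequence ", k, " ('", s, "') is shorter than 2 bases",
           call. = FALSE)
    }
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% names(.base_complement))
    if (length(bad) > 0) {
      stop("sequence ", k, " contains invalid character '",
           chars[bad[1]], "' at position ", bad[1],
           " (allowed: A, C, G, T)", call. = FALSE)
    }
  }
  out
}

#' Antiparallel Watson-Crick complement
#'
#' Complements each base (A<->T, G<->C) and reverses the string, so the
#' result is again read N -> C. The operation is an involution.
#'
#' @param sequence Character vector of PNA sequences.
#' @return Character vector of complements, same length.
#' @export
#' @examples
#' antiparallel_complement("GTAGATCACT") # "AGTGATCTAC"
antiparallel_complement <- function(sequence) {
  sequence <- validate_sequence(sequence)
  vapply(sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    paste(rev(unname(.base_complement[chars])), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Is a strand its own antiparallel complement?
#'
#' Self-complementary strands form homoduplexes with C2 rotational
#' symmetry; their binding entropy carries a symmetry decrement (see
#' [symmetry_correction()]). Odd-length strands are never
#' self-complementary.
#'
#' @inheritParams antiparallel_complement
#' @return Logical vector.
#' @export
#' @examples
#' is_self_complementary(c("CGATCG", "AACGTT", "GTAGATCACT"))
is_self_complementary <- function(sequence) {
  sequence <- validate_sequence(sequence)
  sequence == antiparallel_complement(sequence)
}

#' Canonicalize a dinucleotide stack label
#'
#' Maps each dinucleotide to its canonical class under the
#' antiparallel-duplex equivalence `X1X2 == comp(X2)comp(X1)`: the six
#' non-canonical labels map as TT->AA, CT->AG, TC->GA, GT->AC, TG->CA,
#' CC->GG; the ten canonical labels map to themselves.
#'
#' @param dinucleotide Character vector of two-base strings.
#' @return Character vector of canonical stack labels.
#' @export
#' @examples
#' canonical_stack(c("GT", "CC", "GC"))
canonical_stack <- function(dinucleotide) {
  dinucleotide <- toupper(trimws(dinucleotide))
  ok <- nchar(dinucleotide) == 2 &
    !is.na(match(substr(dinucleotide, 1, 1), names(.base_complement))) &
    !is.na(match(substr(dinucleotide, 2, 2), names(.base_complement)))
  if (any(!ok)) {
    stop("invalid dinucleotide '", dinucleotide[which(!ok)[1]],
         "': expected two bases from A, C, G, T", call. = FALSE)
  }
  vapply(dinucleotide, function(d) {
    if (d %in% .stack_order) return(d)
    chars <- strsplit(d, "", fixed = TRUE)[[1]]
    paste0(.base_complement[chars[2]], .base_complement[chars[1]])
  }, character(1), USE.NAMES = FALSE)
}

#' Describe PNA homoduplexes: stacks, termini, symmetry
#'
#' Enumerates the `length - 1` overlapping dinucleotide stacks of each
#' strand (the second pair of one stack is the first pair of the next),
#' canonicalizes them, and counts occurrences per class. Also records the
#' number of terminal G.C base pairs (0, 1 or 2, from the first and last
#' base of the strand), the terminal-GC indicator used by the
#' nearest-neighbor model (1 only when both termini pair G.C), and
#' self-complementarity.
#'
#' @param data A data frame with a `sequence` column, or a character
#'   vector of sequences.
#' @return A tibble with one row per input sequence: `sequence`, `length`,
#'   one integer count column per canonical stack (AA ... CG), `init`
#'   (always 1), `n_terminal_gc`, `terminal_gc` (0/1 indicator) and
#'   `self_complementary`.
#' @export
#' @examples
#' describe_duplex(c("CGATCG", "AACGTT"))
describe_duplex <- function(data) {
  sequence <- if (is.data.frame(data)) {
    if (!"sequence" %in% names(data)) {
      stop("`data` must contain a `sequence` column", call. = FALSE)
    }
    data$sequence
  } else {
    data
  }
  sequence <- validate_sequence(sequence)

  rows <- purrr::map(sequence, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(chars)
    dints <- paste0(chars[-n], chars[-1])
    canon <- canonical_stack(dints)
    counts <- table(factor(canon, levels = .stack_order))
    n_tgc <- sum(chars[c(1, n)] %in% c("G", "C"))
    c(as.integer(counts),
      n_terminal_gc = n_tgc,
      terminal_gc = as.integer(n_tgc == 2L))
  })
  mat <- do.call(rbind, rows)

  tibble::tibble(
    sequence = sequence,
    length = nchar(sequence),
    !!!as.data.frame(mat[, seq_along(.stack_order), drop = FALSE]) |>
      stats::setNames(.stack_order),
    init = 1L,
    n_terminal_gc = as.integer(mat[, "n_terminal_gc"]),
    terminal_gc = as.integer(mat[, "terminal_gc"]),
    self_complementary = is_self_complementary(sequence)
  )
}

#' Read PNA sequences from a text or FASTA file
#'
#' Plain-text files hold one sequence per line; blank lines and lines
#' starting with `#` are ignored. Files whose first non-blank line starts
#' with `>` are parsed as FASTA (via the seqinr package); headers become
#' labels.
#'
#' @param path Path to the file.
#' @return A tibble with columns `label` and `sequence` (validated,
#'   uppercase).
#' @export
read_pna_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonblank <- lines[trimws(lines) != ""]
  if (length(nonblank) == 0) {
    stop("no sequences found in '", path, "'", call. = FALSE)
  }
  if (startsWith(trimws(nonblank[1]), ">")) {
    if (!requireNamespace("seqinr", quietly = TRUE)) {
      stop("reading FASTA requires the seqinr package", call. = FALSE)
    }
    recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
    seqs <- validate_sequence(unname(vapply(recs, as.character, character(1))))
    return(tibble::tibble(label = names(recs), sequence = seqs))
  }
  keep <- nonblank[!startsWith(trimws(nonblank), "#")]
  seqs <- validate_sequence(keep)
  tibble::tibble(label = paste0("seq", seq_along(seqs)), sequence = seqs)
}
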