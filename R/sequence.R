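# Base-level sequence utilities: normalization, 2-bit codes, reverse complement,
# and the delta strand-decision operator with its rolling update.

# Lookup table: ASCII code -> base code (A=0, C=1, G=2, T=3), NA for N.
.BASE_LUT <- local({
  lut <- rep(-1L, 256L)
  lut[utf8ToInt("A")] <- 0L
  lut[utf8ToInt("C")] <- 1L
  lut[utf8ToInt("G")] <- 2L
  lut[utf8ToInt("T")] <- 3L
  lut[utf8ToInt("N")] <- NA_integer_
  lut
})

#' Normalize a DNA sequence string
#'
#' Uppercases the input (soft-masked lowercase bases are treated as their
#' uppercase equivalents, not as ambiguous) and checks that every character is
#' one of `A`, `C`, `G`, `T`, `N`.
#'
#' @param x Character vector of DNA sequences.
#' @return The normalized character vector.
#' @export
normalize_sequence <- function(x) {
  if (!is.character(x) || length(x) < 1L) {
    abort("`x` must be a character vector of DNA sequences.")
  }
  x <- toupper(x)
  bad <- !grepl("^[ACGTN]+$", x)
  if (any(bad)) {
    chars <- unique(strsplit(gsub("[ACGTN]", "", x[bad][1L]), "")[[1L]])
    abort(paste0(
      "Invalid character(s) in sequence: ",
      paste(sQuote(chars), collapse = ", "),
      ". Allowed alphabet is {A, C, G, T, N} (case-insensitive)."
    ))
  }
  x
}

# String -> integer codes (0..3, NA for N). Assumes a normalized sequence.
.base_codes <- function(seq) {
  .BASE_LUT[utf8ToInt(seq)]
}

# Integer codes -> string. NA codes become N.
.codes_to_seq <- function(codes) {
  out <- character(length(codes))
  out[] <- "N"
  ok <- !is.na(codes)
  out[ok] <- c("A", "C", "G", "T")[codes[ok] + 1L]
  paste(out, collapse = "")
}

# Reverse complement on the code scale (complement = 3 - code, order reversed).
.revcomp_codes <- function(codes) {
  rev(3L - codes)
}

#' Reverse complement
#'
#' A <-> T, C <-> G, N <-> N, order reversed. Vectorized over sequences; an
#' involution on its domain.
#'
#' @param x Character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("CAAAGTAAGCT")
#' @export
reverse_complement <- function(x) {
  x <- normalize_sequence(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Window strand-decision operator delta
#'
#' For a window `s`, `delta(s) = pT + pG - pC - pA` where `pA..pT` are base
#' occurrence counts. For odd window lengths delta is never zero, and it is
#' antisymmetric under reverse complement: `delta(revcomp(s)) = -delta(s)`.
#' The sign of delta decides which strand of the window the refined minimizer
#' scans.
#'
#' @param window Character vector of windows over `{A,C,G,T}` (no ambiguous
#'   bases: delta is undefined on `N`).
#' @return Integer vector of delta values.
#' @examples
#' delta("CAAAGTAAGCT") # -3
#' @export
delta <- function(window) {
  window <- normalize_sequence(window)
  vapply(window, function(s) {
    codes <- .base_codes(s)
    if (anyNA(codes)) {
      abort("delta is undefined on windows containing ambiguous bases (N).")
    }
    sum(codes >= 2L) - sum(codes < 2L)
  }, integer(1), USE.NAMES = FALSE)
}

#' Rolling delta state for a streaming window
#'
#' Builds the base-count state of a window so that sliding the window by one
#' base can update delta in O(1) with [delta_update()].
#'
#' @param window A single window string over `{A,C,G,T}`.
#' @return An object of class `delta_state` with fields `counts` (named counts
#'   of A, C, G, T), `delta`, and `window_length`.
#' @export
delta_state <- function(window) {
  window <- normalize_sequence(window)
  stopifnot(length(window) == 1L)
  codes <- .base_codes(window)
  if (anyNA(codes)) {
    abort(paste0(
      "Rolling delta state is invalid over ambiguous bases (N); ",
      "recount once the N leaves scope."
    ))
  }
  counts <- vapply(0:3, function(b) sum(codes == b), integer(1))
  names(counts) <- c("A", "C", "G", "T")
  structure(
    list(
      counts = counts,
      delta = unname(counts["T"] + counts["G"] - counts["C"] - counts["A"]),
      window_length = length(codes)
    ),
    class = "delta_state"
  )
}

#' @export
print.delta_state <- function(x, ...) {
  cat("<delta_state> |s| =", x$window_length, " delta =", x$delta, "\n")
  print(x$counts)
  invisible(x)
}

#' Slide the window by one base and update delta in O(1)
#'
#' Applies the rolling increment: +2 if the outgoing base is in `{A,C}` and the
#' incoming base in `{G,T}`; -2 in the opposite case; 0 when both bases fall in
#' the same complement class.
#'
#' @param state A `delta_state` from [delta_state()].
#' @param outgoing The base leaving the window (its first base).
#' @param incoming The base entering the window (appended at the end).
#' @return The updated `delta_state`.
#' @examples
#' st <- delta_state("AGCTTACTTTG") # delta = 3
#' delta_update(st, "A", "G")$delta # 5
#' @export
delta_update <- function(state, outgoing, incoming) {
  if (!inherits(state, "delta_state")) {
    abort("`state` must be a `delta_state` object.")
  }
  outgoing <- toupper(outgoing)
  incoming <- toupper(incoming)
  if (outgoing == "N" || incoming == "N") {
    abort(paste0(
      "Ambiguous base (N) entering or leaving the window invalidates the ",
      "rolling state; a fresh recount is required once the N leaves scope."
    ))
  }
  if (!outgoing %in% c("A", "C", "G", "T") || !incoming %in% c("A", "C", "G", "T")) {
    abort("`outgoing` and `incoming` must be single bases in {A, C, G, T}.")
  }
  if (state$counts[outgoing] < 1L) {
    abort(paste0("Outgoing base ", sQuote(outgoing), " is not present in the window."))
  }
  out_gt <- outgoing %in% c("G", "T")
  in_gt <- incoming %in% c("G", "T")
  d <- if (out_gt == in_gt) 0L else if (in_gt) 2L else -2L
  state$counts[outgoing] <- state$counts[outgoing] - 1L
  state$counts[incoming] <- state$counts[incoming] + 1L
  state$delta <- state$delta + d
  state
}

#' Complement pairs of q-mers
#'
#' Enumerates the unordered pairs `{r, revcomp(r)}` of non-palindromic q-mers,
#' ordered by the lexicographic rank of the greater member (which carries the
#' positive sign in [extended_delta()]). For odd `q` there are exactly `4^q/2`
#' pairs; for even `q`, palindromic q-mers (equal to their own reverse
#' complement) contribute nothing to the operator and are excluded.
#'
#' @param q Gram length (>= 1).
#' @return A tibble with columns `kmer` (greater member), `revcomp`, and their
#'   lexicographic ranks.
#' @export
delta_pairs <- function(q) {
  stopifnot(q >= 1, q == as.integer(q))
  ranks <- 0:(4^q - 1)
  kmers <- decode_kmer(ranks, q)
  rc <- reverse_complement(kmers)
  rc_rank <- encode_kmer(rc)
  keep <- ranks > rc_rank
  tibble(
    kmer = kmers[keep],
    revcomp = rc[keep],
    rank = ranks[keep],
    revcomp_rank = rc_rank[keep]
  ) |>
    dplyr::arrange(.data$rank)
}

#' Extended delta over q-mer composition
#'
#' Generalizes the single-base operator to overlapping q-mer counts:
#' `sum_i w_i * (p(q_i) - p(q_i'))` over complement pairs `{q_i, q_i'}`, where
#' `q_i` is the lexicographically greater member. With `q = 1` and unit weights
#' this is exactly [delta()]. Weights must be odd integers so that the operator
#' is never zero on odd-length windows (for `q = 1`).
#'
#' @param window A single window string over `{A,C,G,T}`, length >= `q`.
#' @param q Gram length.
#' @param weights Odd integer weights, one per complement pair in the order of
#'   [delta_pairs()]; default all 1.
#' @return The weighted composition score (integer-valued numeric).
#' @export
extended_delta <- function(window, q = 1L, weights = NULL) {
  window <- normalize_sequence(window)
  stopifnot(length(window) == 1L)
  pairs <- delta_pairs(q)
  if (is.null(weights)) weights <- rep(1L, nrow(pairs))
  if (length(weights) != nrow(pairs)) {
    abort(paste0(
      "`weights` must have one entry per complement pair: expected ",
      nrow(pairs), " for q = ", q, "."
    ))
  }
  if (any(weights %% 2 != 1)) {
    abort("All extended-delta weights must be odd integers.")
  }
  codes <- .base_codes(window)
  if (anyNA(codes)) {
    abort("extended_delta is undefined on windows containing ambiguous bases (N).")
  }
  if (length(codes) < q) abort("`window` must be at least `q` bases long.")
  qcodes <- .kmer_codes(codes, q)
  counts <- tabulate(qcodes + 1L, nbins = 4^q)
  sum(weights * (counts[pairs$rank + 1L] - counts[pairs$revcomp_rank + 1L]))
}
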