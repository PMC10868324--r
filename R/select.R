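# Per-window minimizer selection by direct enumeration of all candidate
# k-mers. This is the reference path; stream_minimizers() uses a rolling
# vectorized pipeline and is tested against these functions window by window.

# Candidate table for one window: all forward k-mers and all reverse-complement
# k-mers with forward-strand coordinates. `codes` are the window's base codes.
.window_candidates <- function(codes, k, scheme) {
  len <- length(codes)
  w <- len - k + 1L
  fwd <- .kmer_codes(codes, k)
  rc <- .kmer_codes(.revcomp_codes(codes), k)
  tibble(
    code = c(fwd, rc),
    rank = c(.rank_codes(fwd, scheme), .rank_codes(rc, scheme)),
    # offset i on the reverse complement starts at forward position len-k-i
    fwd_start = c(0:(w - 1L), (len - k) - (0:(w - 1L))),
    strand = rep(c("+", "-"), each = w)
  )
}

# Deterministic tie-breaking: minimum rank, then lowest forward start, then '+'.
.pick_candidate <- function(cand) {
  cand[order(cand$rank, cand$fwd_start, cand$strand), ][1L, ]
}

.selection_record <- function(window, pick, k, mode, dlt) {
  tibble(
    window_index = 0L,
    fwd_start = as.integer(pick$fwd_start),
    end = as.integer(pick$fwd_start + k),
    kmer = if (pick$strand == "+") {
      substr(window, pick$fwd_start + 1L, pick$fwd_start + k)
    } else {
      reverse_complement(substr(window, pick$fwd_start + 1L, pick$fwd_start + k))
    },
    rank = pick$rank,
    strand = pick$strand,
    delta = as.integer(dlt),
    mode = mode
  )
}

.check_window <- function(window, k) {
  window <- normalize_sequence(window)
  stopifnot(length(window) == 1L)
  if (nchar(window) < k) abort("`window` is shorter than k.")
  codes <- .base_codes(window)
  if (anyNA(codes)) {
    abort("Window contains ambiguous bases (N); no minimizer is defined.")
  }
  list(window = window, codes = codes)
}

#' Standard canonical minimizer of a single window
#'
#' Selects the minimum-rank k-mer jointly over the window's `w` forward k-mers
#' and the `w` k-mers of its reverse complement, so the selection is
#' strand-independent. Ties are broken by the lowest forward-strand start, then
#' by the forward strand.
#'
#' @param window A window string of length `w + k - 1` over `{A,C,G,T}`.
#' @param k k-mer length.
#' @param scheme An [order_scheme()] with matching `k`; defaults to
#'   lexicographic.
#' @return A one-row tibble with columns `window_index`, `fwd_start`, `end`
#'   (0-based half-open), `kmer` (oriented as selected), `rank`, `strand`,
#'   `delta`, `mode`.
#' @examples
#' select_standard("CAAAGTAAGCT", k = 5) # AAAGT, rank 11
#' @export
select_standard <- function(window, k, scheme = order_scheme("lexicographic", k)) {
  chk <- .check_window(window, k)
  cand <- .window_candidates(chk$codes, k, scheme)
  dlt <- sum(chk$codes >= 2L) - sum(chk$codes < 2L)
  .selection_record(chk$window, .pick_candidate(cand), k, "standard", dlt)
}

#' Refined canonical minimizer of a single window
#'
#' Computes `delta(window)` and scans a single strand: the window's forward
#' k-mers when `delta > 0`, the reverse complement's k-mers when `delta < 0`.
#' Because delta is antisymmetric and nonzero on odd-length windows, the result
#' is identical for a window and its reverse complement (strand symmetry), and
#' its rank is never below the standard selection's (dominance).
#'
#' @inheritParams select_standard
#' @return A one-row tibble as in [select_standard()]; `strand` is `"+"` when
#'   the window's own strand was scanned.
#' @examples
#' select_refined("CAAAGTAAGCT", k = 5) # ACTTT, rank 127, strand "-"
#' @export
select_refined <- function(window, k, scheme = order_scheme("lexicographic", k)) {
  chk <- .check_window(window, k)
  if (length(chk$codes) %% 2L == 0L) {
    abort("Refined selection requires an odd window length (so that delta != 0).")
  }
  dlt <- sum(chk$codes >= 2L) - sum(chk$codes < 2L)
  cand <- .window_candidates(chk$codes, k, scheme)
  side <- if (dlt > 0) "+" else "-"
  .selection_record(
    chk$window, .pick_candidate(cand[cand$strand == side, ]), k, "refined", dlt
  )
}
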