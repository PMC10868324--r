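# Streaming minimizer selection over whole sequences. The engine is fully
# vectorized: 2-bit k-mer codes are built in k passes, window delta comes from
# one cumulative sum (the rolling increment in closed form), and the sliding
# window minimum is maintained with w pmin-style passes per strand.

.RECORD_COLS <- c(
  "seqname", "window_index", "fwd_start", "end", "kmer", "rank",
  "strand", "delta", "mode"
)

.empty_records <- function() {
  tibble(
    seqname = character(), window_index = integer(), fwd_start = integer(),
    end = integer(), kmer = character(), rank = numeric(), strand = character(),
    delta = integer(), mode = character()
  )
}

# Sliding-window minimum over `w` consecutive entries of `x` with an argmin;
# ties keep the earliest offset (the leftmost forward coordinate).
.sliding_min <- function(x, w) {
  nw <- length(x) - w + 1L
  cur <- x[seq_len(nw)]
  arg <- integer(nw)
  if (w > 1L) {
    for (j in seq_len(w - 1L)) {
      cand <- x[(1L + j):(nw + j)]
      better <- cand < cur
      cur[better] <- cand[better]
      arg[better] <- j
    }
  }
  list(min = cur, arg = arg)
}

# Keep-mask from the solo heuristic applied within one contiguous run of
# windows (no N gaps): a window is dropped iff its delta sign differs from
# both neighbours; run boundaries are never solo.
.solo_keep <- function(dlt) {
  n <- length(dlt)
  if (n < 3L) return(rep(TRUE, n))
  s <- sign(dlt)
  keep <- rep(TRUE, n)
  mid <- 2:(n - 1L)
  keep[mid] <- !(s[mid] != s[mid - 1L] & s[mid] != s[mid + 1L])
  keep
}

#' Solo-window keep mask from a delta trace
#'
#' A "solo" window is one whose delta sign differs from both its predecessor
#' and successor; skipping solo windows trims the refined scheme's extra
#' density while leaving non-solo selections recoverable from neighbouring
#' windows. The first and last windows have a single neighbour and are never
#' classified solo.
#'
#' @param delta_trace Integer vector of per-window delta values, all nonzero.
#' @return Logical vector, `TRUE` for windows to keep.
#' @examples
#' solo_window_mask(c(-1, 1, -1)) # keep, skip, keep
#' @export
solo_window_mask <- function(delta_trace) {
  if (length(delta_trace) == 0L) return(logical(0))
  if (any(delta_trace == 0)) {
    abort("Zero delta in trace: the solo heuristic requires odd window lengths.")
  }
  .solo_keep(delta_trace)
}

#' Stream minimizers over a sequence
#'
#' Slides a window of `w` consecutive k-mers (length `w + k - 1`) one base at a
#' time over the sequence and selects, per window, the standard canonical
#' minimizer (minimum rank over both strands) or the refined minimizer (the
#' window delta sign picks a single strand to scan). Windows overlapping an
#' ambiguous base (`N`) emit no record; streaming resumes at the next N-free
#' window. The output is identical to calling [select_standard()] /
#' [select_refined()] on every window.
#'
#' @param seq A single DNA sequence string (or a one-row data frame with
#'   columns `name` and `seq`, as returned by [read_fasta()]).
#' @param k k-mer length.
#' @param w Number of k-mers per window. `w + k - 1` must be odd in refined
#'   mode.
#' @param scheme An [order_scheme()]; defaults to lexicographic.
#' @param mode `"standard"` or `"refined"`.
#' @param heuristic `"none"` or `"solo_skip"` (drop solo windows; see
#'   [solo_window_mask()]).
#' @param collapse If `TRUE` (default), consecutive windows selecting the same
#'   occurrence (same `fwd_start` and `strand`) are emitted once with the
#'   earliest `window_index` — the distinct-occurrence convention under which
#'   the expected density is about `2/(w+1)`. If `FALSE`, one record per
#'   window (the per-window view used in worked examples).
#' @param seqname Sequence name for the `seqname` column when `seq` is a bare
#'   string.
#' @param quiet Suppress the informational message about skipped windows.
#' @return A tibble with columns `seqname`, `window_index` (0-based),
#'   `fwd_start`, `end` (0-based half-open), `kmer` (oriented as selected),
#'   `rank`, `strand`, `delta` (delta of the streamed window), `mode`.
#' @examples
#' stream_minimizers("AGCTTACTTTGGTGTTTGGTAAATG", k = 5, w = 7, mode = "refined")
#' @export
stream_minimizers <- function(seq, k, w,
                              scheme = order_scheme("lexicographic", k),
                              mode = c("standard", "refined"),
                              heuristic = c("none", "solo_skip"),
                              collapse = TRUE,
                              seqname = "seq",
                              quiet = FALSE) {
  mode <- match.arg(mode)
  heuristic <- match.arg(heuristic)
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1L, all(c("name", "seq") %in% names(seq)))
    seqname <- seq$name
    seq <- seq$seq
  }
  seq <- normalize_sequence(seq)
  stopifnot(length(seq) == 1L, k >= 1, w >= 1)
  if (!inherits(scheme, "order_scheme") || scheme$k != k) {
    abort("`scheme` must be an `order_scheme` with matching k.")
  }
  len <- as.integer(w + k - 1L)
  needs_delta <- mode == "refined" || heuristic == "solo_skip"
  if (needs_delta && len %% 2L == 0L) {
    abort(paste0(
      "Window length |s| = w + k - 1 = ", len, " must be odd in refined mode ",
      "(and for the solo heuristic), so that delta is never zero."
    ))
  }
  n <- nchar(seq)
  if (n < len) {
    warn("Sequence is shorter than one window; returning no records.")
    return(.empty_records())
  }

  codes <- .base_codes(seq)
  isn <- is.na(codes)
  codes0 <- codes
  codes0[isn] <- 0L

  nw <- n - len + 1L
  # window validity: no N inside [p, p+len-1]
  cn <- cumsum(isn)
  valid <- (cn[seq_len(nw) + len - 1L] - c(0L, cn)[seq_len(nw)]) == 0L

  # per-position k-mer ranks on both strands; positions spanning an N get +Inf
  # (they only occur inside invalid windows, which are masked out below)
  fk <- .rank_codes(.kmer_codes(codes0, k), scheme)
  rk <- .rank_codes(.rc_kmer_codes(codes0, k), scheme)
  nk <- n - k + 1L
  kbad <- (cn[seq_len(nk) + k - 1L] - c(0L, cn)[seq_len(nk)]) > 0L
  fk[kbad] <- Inf
  rk[kbad] <- Inf

  # window delta from one cumulative sum of the +/-1 base classes
  v <- ifelse(codes0 >= 2L, 1L, -1L)
  v[isn] <- 0L
  cv <- cumsum(v)
  dwin <- as.integer(cv[seq_len(nw) + len - 1L] - c(0, cv)[seq_len(nw)])

  # both rank vectors are indexed by forward k-mer start, so the earliest
  # offset is the lowest forward coordinate on either strand
  smf <- .sliding_min(fk, w)
  smr <- .sliding_min(rk, w)
  p0 <- seq_len(nw) - 1L # 0-based window starts
  f_start <- p0 + smf$arg
  r_start <- p0 + smr$arg

  if (mode == "standard") {
    take_f <- smf$min < smr$min |
      (smf$min == smr$min & f_start <= r_start)
  } else {
    take_f <- dwin > 0L
  }
  rank <- ifelse(take_f, smf$min, smr$min)
  fwd_start <- as.integer(ifelse(take_f, f_start, r_start))
  strand <- ifelse(take_f, "+", "-")

  keep <- valid
  n_solo <- 0L
  if (heuristic == "solo_skip") {
    solo_keep <- rep(TRUE, nw)
    runs <- rle(valid)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in seq_along(runs$values)) {
      if (runs$values[i]) {
        idx <- starts[i]:ends[i]
        solo_keep[idx] <- .solo_keep(dwin[idx])
      }
    }
    n_solo <- sum(valid & !solo_keep)
    keep <- keep & solo_keep
  }

  if (!quiet) {
    n_nskip <- sum(!valid)
    if (n_nskip > 0L || n_solo > 0L) {
      inform(paste0(
        seqname, ": skipped ", n_nskip, " window(s) overlapping N and ",
        n_solo, " solo window(s) out of ", nw, "."
      ))
    }
  }

  out <- tibble(
    seqname = seqname,
    window_index = p0[keep],
    fwd_start = fwd_start[keep],
    end = fwd_start[keep] + as.integer(k),
    rank = rank[keep],
    strand = strand[keep],
    delta = dwin[keep],
    mode = mode
  )
  if (collapse && nrow(out) > 1L) {
    occ <- paste0(out$fwd_start, out$strand)
    first <- c(TRUE, occ[-1L] != occ[-length(occ)])
    out <- out[first, ]
  }
  fwd_kmer <- substring(seq, out$fwd_start + 1L, out$fwd_start + k)
  neg <- out$strand == "-"
  if (any(neg)) {
    fwd_kmer[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(fwd_kmer[neg]))
    )
  }
  out$kmer <- fwd_kmer
  out[, .RECORD_COLS]
}

#' Sketch minimizers over a set of sequences
#'
#' Data-frame-first wrapper around [stream_minimizers()]: takes the tibble of
#' sequences returned by [read_fasta()] (columns `name`, `seq`) and returns the
#' row-bound records of all sequences. The total number of bases scanned is
#' attached as attribute `seq_length` (used by [minimizer_stats()] defaults).
#'
#' @param seqs A data frame with columns `name` and `seq`, or a (possibly
#'   named) character vector of sequences.
#' @inheritParams stream_minimizers
#' @param ... Passed on to [stream_minimizers()].
#' @return A tibble of minimizer records (see [stream_minimizers()]).
#' @examples
#' sk <- sketch_minimizers(make_fixture("table2")$sequence, k = 5, w = 7,
#'                         mode = "refined")
#' @export
sketch_minimizers <- function(seqs, k, w, ...) {
  if (!is.data.frame(seqs)) {
    nm <- names(seqs)
    if (is.null(nm)) nm <- paste0("seq", seq_along(seqs))
    seqs <- tibble(name = nm, seq = unname(seqs))
  }
  stopifnot(all(c("name", "seq") %in% names(seqs)))
  out <- purrr::map2(
    seqs$name, seqs$seq,
    function(nm, s) stream_minimizers(s, k = k, w = w, seqname = nm, ...)
  ) |>
    dplyr::bind_rows()
  attr(out, "seq_length") <- sum(nchar(seqs$seq))
  out
}
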