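# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's encoding arithmetic and sliding-window machinery.

# Lexicographic rank via digit translation and base-4 string parsing.
oracle_lex_rank <- function(kmer) {
  vapply(kmer, function(s) strtoi(chartr("ACGT", "0123", s), base = 4L),
         numeric(1), USE.NAMES = FALSE)
}

# Reverse complement by explicit per-character mapping.
oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
}

oracle_delta <- function(s) {
  ch <- strsplit(s, "")[[1]]
  sum(ch %in% c("T", "G")) - sum(ch %in% c("C", "A"))
}

# All k-mer substrings of a sequence.
oracle_kmers <- function(s, k) {
  n <- nchar(s)
  substring(s, 1:(n - k + 1L), k:n)
}

# Per-window selection by full candidate enumeration over strings; returns the
# selected k-mer, its rank, forward start (window-local, 0-based) and strand.
oracle_select <- function(window, k, scheme, mode) {
  len <- nchar(window)
  w <- len - k + 1L
  fwd <- oracle_kmers(window, k)
  rcw <- oracle_revcomp(window)
  rck <- oracle_kmers(rcw, k)
  cand <- data.frame(
    kmer = c(fwd, rck),
    fwd_start = c(0:(w - 1L), (len - k) - (0:(w - 1L))),
    strand = rep(c("+", "-"), each = w),
    stringsAsFactors = FALSE
  )
  cand$rank <- kmer_rank(cand$kmer, scheme)
  if (mode == "refined") {
    d <- oracle_delta(window)
    cand <- cand[cand$strand == (if (d > 0) "+" else "-"), ]
  }
  cand <- cand[order(cand$rank, cand$fwd_start, cand$strand), ]
  cand[1L, ]
}

# Naive per-window streaming: oracle_select applied to every N-free window,
# coordinates shifted to the global frame.
oracle_stream <- function(seq, k, w, scheme, mode) {
  len <- w + k - 1L
  n <- nchar(seq)
  rows <- lapply(0:(n - len), function(p) {
    win <- substr(seq, p + 1L, p + len)
    if (grepl("N", win, fixed = TRUE)) return(NULL)
    sel <- oracle_select(win, k, scheme, mode)
    data.frame(
      window_index = p, fwd_start = sel$fwd_start + p, kmer = sel$kmer,
      rank = sel$rank, strand = sel$strand, delta = oracle_delta(win),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Quantile by sorting and linear interpolation between order statistics.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Random window strings over ACGT of a given length.
random_windows <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Distinct occurrence keys of a record tibble.
occurrence_keys <- function(records) {
  unique(paste(records$seqname, records$fwd_start, records$strand))
}
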