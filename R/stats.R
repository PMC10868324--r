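# Evaluation statistics for a minimizer selection: density, k-mer frequency,
# percentiles, KL divergence against the uniform k-mer distribution, expected
# hits, and the expected per-type occurrence coefficient.

# Unique selected occurrences: one row per (seqname, fwd_start, strand).
.distinct_occurrences <- function(records) {
  dplyr::distinct(records, .data$seqname, .data$fwd_start, .data$strand,
                  .keep_all = TRUE)
}

#' Minimizer density
#'
#' The fraction `|X| / |S|` of sequence positions carrying a selected
#' occurrence, where `|X|` counts distinct `(seqname, fwd_start, strand)`
#' selections. For random orders on random sequences the expectation is about
#' `2 / (w + 1)`.
#'
#' @param records A tibble of minimizer records ([stream_minimizers()]).
#' @param seq_length Total number of bases scanned.
#' @return The density (scalar in `(0, 1]`; `0` with a warning when `records`
#'   is empty).
#' @export
minimizer_density <- function(records, seq_length) {
  stopifnot(seq_length >= 1)
  if (nrow(records) == 0L) {
    warn("Empty selection: density is 0.")
    return(0)
  }
  nrow(.distinct_occurrences(records)) / seq_length
}

#' k-mer frequency table of a selection
#'
#' Counts `n(x)` of each selected (oriented) k-mer value among the distinct
#' occurrences, with the per-base frequency `v(x) = n(x) / |S|` and its
#' per-megabase scaling.
#'
#' @inheritParams minimizer_density
#' @return A tibble with columns `kmer`, `n`, `v` (= `n / seq_length`) and
#'   `v_per_mb` (= `v * 1e6`), sorted by decreasing `n`.
#' @export
frequency_table <- function(records, seq_length) {
  stopifnot(seq_length >= 1)
  out <- .distinct_occurrences(records) |>
    dplyr::count(.data$kmer, name = "n") |>
    dplyr::mutate(v = .data$n / seq_length, v_per_mb = .data$v * 1e6) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$kmer)
  attr(out, "seq_length") <- NULL
  out
}

#' Empirical quantiles of per-megabase minimizer frequencies
#'
#' Quantiles over the distinct k-mer values present in the selection
#' (unweighted), with linear interpolation between order statistics.
#'
#' @param freq_values Numeric vector of per-megabase frequencies (one per
#'   distinct k-mer value), e.g. `frequency_table(...)$v_per_mb`.
#' @param probs Quantile levels in `(0, 1)`.
#' @return A tibble with columns `prob` and `value`.
#' @export
freq_percentiles <- function(freq_values, probs = c(0.25, 0.5, 0.75, 0.95)) {
  if (length(freq_values) == 0L) abort("`freq_values` must be nonempty.")
  stopifnot(all(probs > 0 & probs < 1))
  tibble(
    prob = probs,
    value = unname(quantile(freq_values, probs = probs, type = 7))
  )
}

#' Kullback-Leibler divergence against the uniform k-mer distribution
#'
#' `D_KL(X || U) = sum_x p(x) log(p(x) / u(x))` in nats, with
#' `p(x) = n(x) / |X|` the empirical distribution of selected k-mer values and
#' `u(x) = 1 / 4^k` uniform over all `4^k` k-mers. Zero-count terms vanish
#' (`0 log 0 := 0`), so the sum over the support is exact for any `k`. Lower
#' divergence means the scheme is less biased toward specific k-mers.
#'
#' @param counts Integer vector of k-mer counts `n(x)` (the support; zeros
#'   allowed and ignored).
#' @param k k-mer length.
#' @return The divergence in nats (>= 0; 0 iff uniform over all `4^k` k-mers).
#' @export
kl_divergence <- function(counts, k) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) abort("`counts` must contain at least one selection.")
  p <- counts / sum(counts)
  sum(p * (log(p) + k * log(4)))
}

#' Expected hits of a selection
#'
#' `E-hits(X) = (sum_x n(x)^2) / |X|`: the expected number of occurrences in
#' `X` sharing the k-mer value of a uniformly drawn selected occurrence. A
#' joint measure of density and repetitiveness; 1 when every selected k-mer
#' value is unique.
#'
#' @param counts Integer vector of k-mer counts `n(x)`.
#' @return The expected-hits statistic (>= 1 for nonempty selections).
#' @export
e_hits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) abort("`counts` must contain at least one selection.")
  sum(counts^2) / sum(counts)
}

#' Expected occurrences per k-mer type
#'
#' `E(X, k) = rho |S| / 4^k ~ 2 |S| / ((w + 1) 4^k)`: the average number of
#' selected occurrences per k-mer type. When it is near zero (large `k`,
#' moderate `|S|`), most k-mer types never appear in the selection and
#' empirical frequency distributions are dominated by small-sample effects.
#'
#' @param seq_length `|S|` in bases.
#' @param window_length `|s| = w + k - 1` in bases.
#' @param k k-mer length.
#' @param density Optional observed density; if supplied, `density * seq_length
#'   / 4^k` is returned instead of the `2/(w+1)` approximation.
#' @return Expected occurrence count per k-mer type.
#' @export
expected_occurrence <- function(seq_length, window_length, k, density = NULL) {
  stopifnot(window_length >= k)
  if (!is.null(density)) {
    return(density * seq_length / 4^k)
  }
  w <- window_length - k + 1
  2 * seq_length / ((w + 1) * 4^k)
}

#' Running median and range of a rank trace
#'
#' After each window `n`, the median and range (max - min) of the per-window
#' minimizer ranks over windows `1..n`. The median of an even-length prefix is
#' the upper-middle order statistic (`sorted[n %/% 2 + 1]`), the convention
#' under which the worked-example table in [make_fixture()] reproduces
#' exactly.
#'
#' @param rank_trace Numeric vector of per-window ranks.
#' @return A tibble with columns `step`, `median`, `range`.
#' @export
running_summary <- function(rank_trace) {
  n <- length(rank_trace)
  if (n == 0L) abort("`rank_trace` must be nonempty.")
  med <- numeric(n)
  rng <- numeric(n)
  for (i in seq_len(n)) {
    x <- sort(rank_trace[seq_len(i)])
    med[i] <- x[i %/% 2L + 1L]
    rng[i] <- x[i] - x[1L]
  }
  tibble(step = seq_len(n), median = med, range = rng)
}

#' Summary statistics of a minimizer selection
#'
#' Bundles the evaluation statistics of a selection: density, the k-mer
#' frequency table, frequency percentiles per megabase, KL divergence against
#' the uniform k-mer distribution, expected hits, and the expected
#' per-k-mer-type occurrence (both the `2/(w+1)` form and the observed-density
#' form).
#'
#' @param records A tibble of minimizer records ([stream_minimizers()] /
#'   [sketch_minimizers()]).
#' @param seq_length Total bases scanned; defaults to the `seq_length`
#'   attribute attached by [sketch_minimizers()].
#' @param window_length `|s| = w + k - 1`; optional, enables the closed-form
#'   expected occurrence.
#' @param probs Percentile levels for the frequency distribution.
#' @return An object of class `minimizer_stats`; see [glance.minimizer_stats()]
#'   and [tidy.minimizer_stats()].
#' @export
minimizer_stats <- function(records, seq_length = attr(records, "seq_length"),
                            window_length = NULL,
                            probs = c(0.25, 0.5, 0.75, 0.95)) {
  if (is.null(seq_length)) {
    abort("`seq_length` must be supplied (total bases scanned).")
  }
  if (nrow(records) == 0L) abort("`records` must contain at least one selection.")
  k <- nchar(records$kmer[1L])
  freq <- frequency_table(records, seq_length)
  pct <- freq_percentiles(freq$v_per_mb, probs)
  rho <- minimizer_density(records, seq_length)
  structure(
    list(
      k = k,
      seq_length = seq_length,
      window_length = window_length,
      mode = records$mode[1L],
      n_selected = sum(freq$n),
      density = rho,
      freq = freq,
      percentiles = pct,
      kl_divergence = kl_divergence(freq$n, k),
      e_hits = e_hits(freq$n),
      e_occ_observed = expected_occurrence(
        seq_length, if (is.null(window_length)) k else window_length, k,
        density = rho
      ),
      e_occ_expected = if (is.null(window_length)) NA_real_ else {
        expected_occurrence(seq_length, window_length, k)
      }
    ),
    class = "minimizer_stats"
  )
}

#' @export
print.minimizer_stats <- function(x, ...) {
  cat("<minimizer_stats>", x$mode, "mode, k =", x$k,
      ", |S| =", x$seq_length, "\n")
  print(glance(x))
  invisible(x)
}

#' One-row summary of minimizer statistics
#'
#' @param x A [minimizer_stats()] object.
#' @param ... Unused.
#' @return A one-row tibble with the scalar statistics and one column per
#'   requested frequency percentile (`p25`, `p50`, ... per megabase).
#' @export
glance.minimizer_stats <- function(x, ...) {
  pct <- setNames(
    as.list(x$percentiles$value),
    paste0("p", round(x$percentiles$prob * 100))
  )
  dplyr::bind_cols(
    tibble(
      mode = x$mode, k = x$k, seq_length = x$seq_length,
      n_selected = x$n_selected, density = x$density,
      kl_divergence = x$kl_divergence, e_hits = x$e_hits,
      e_occ_observed = x$e_occ_observed, e_occ_expected = x$e_occ_expected
    ),
    tibble::as_tibble(pct)
  )
}

#' Frequency table of a minimizer-stats object
#'
#' @param x A [minimizer_stats()] object.
#' @param ... Unused.
#' @return The tibble of per-k-mer counts and frequencies.
#' @export
tidy.minimizer_stats <- function(x, ...) {
  x$freq
}

#' Log-log frequency spectrum of a minimizer selection
#'
#' Plots the empirical distribution of the per-megabase minimizer frequency
#' `V`: for each observed frequency value, the proportion of distinct k-mer
#' values attaining it, on log10-log10 axes. Right-heavy tails indicate
#' repetitive selections.
#'
#' @param object A [minimizer_stats()] object.
#' @param ... Additional `minimizer_stats` objects to overlay (named arguments
#'   become legend labels).
#' @return A ggplot object.
#' @export
autoplot.minimizer_stats <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, inherits, logical(1), "minimizer_stats")]
  objs <- c(list(object), extra)
  labels <- names(objs)
  if (is.null(labels)) labels <- rep("", length(objs))
  labels[labels == ""] <- vapply(objs[labels == ""], function(o) o$mode,
                                 character(1))
  spec <- purrr::map2(objs, make.unique(labels), function(o, lab) {
    o$freq |>
      dplyr::count(.data$v_per_mb, name = "n_kmers") |>
      dplyr::mutate(p = .data$n_kmers / sum(.data$n_kmers), scheme = lab)
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(spec, ggplot2::aes(x = .data$v_per_mb, y = .data$p,
                                     colour = .data$scheme)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "minimizer frequency V (per Mb)",
      y = "empirical P(V = v)",
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
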