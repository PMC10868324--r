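# Random-sequence generators and the analytic operation-cost model used to
# study the refined scheme's limit behaviour.

# Evaluate `expr` under a temporary RNG seed without disturbing the caller's
# RNG state. A NULL seed uses (and advances) the current stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

.codes_to_string <- function(codes) {
  intToUtf8(c(65L, 67L, 71L, 84L)[codes + 1L])
}

#' Simulate an i.i.d. random DNA sequence
#'
#' Bases are drawn independently with `P(A) = P(C) = p_ac / 2` and
#' `P(G) = P(T) = (1 - p_ac) / 2`, the composition model under which the
#' refined scheme's limit properties are stated (`p_ac` is the probability
#' that a base falls in the `{A, C}` complement class, so the per-base
#' expectation of the delta contribution is `1 - 2 p_ac`).
#'
#' @param length Sequence length in bases.
#' @param p_ac Probability of the `{A, C}` class, in `[0, 1]`.
#' @param seed Integer seed; the sequence is reproducible for a fixed seed and
#'   the caller's RNG state is left untouched.
#' @param name Sequence name.
#' @return A one-row tibble with columns `name`, `seq` (pipeable into
#'   [sketch_minimizers()]).
#' @export
simulate_sequence <- function(length, p_ac = 0.5, seed = NULL, name = "sim") {
  stopifnot(length >= 1, p_ac >= 0, p_ac <= 1)
  codes <- .with_seed(seed, {
    ac <- runif(length) < p_ac
    lo <- runif(length) < 0.5
    ifelse(ac, ifelse(lo, 0L, 1L), ifelse(lo, 2L, 3L))
  })
  tibble(name = name, seq = .codes_to_string(codes))
}

#' Simulate a random sequence with injected repeat structure
#'
#' An i.i.d. background (as [simulate_sequence()]) into which two genome-like
#' features are implanted: (i) tandem-free dispersed repeats — a small library
#' of random units, each copied at random positions on either strand; and
#' (ii) short poly-A/poly-T tracts. Both features make the smallest k-mers
#' recur, which is the regime where lexicographic standard minimizers become
#' repetitive and the refined scheme helps.
#'
#' @inheritParams simulate_sequence
#' @param n_units Number of distinct repeat units.
#' @param unit_length Length of each unit (bases).
#' @param copies_per_unit Copies implanted per unit.
#' @param n_tracts Number of poly-A/poly-T tracts.
#' @param tract_length Range (min, max) of tract lengths.
#' @return A one-row tibble with columns `name`, `seq`.
#' @export
simulate_repetitive_sequence <- function(length, p_ac = 0.5, seed = NULL,
                                         name = "sim_rep",
                                         n_units = 10, unit_length = 150,
                                         copies_per_unit = 100,
                                         n_tracts = 1000,
                                         tract_length = c(10, 30)) {
  stopifnot(length > unit_length, length > max(tract_length))
  codes <- .with_seed(seed, {
    ac <- runif(length) < p_ac
    lo <- runif(length) < 0.5
    x <- ifelse(ac, ifelse(lo, 0L, 1L), ifelse(lo, 2L, 3L))
    units <- replicate(n_units, sample(0:3, unit_length, replace = TRUE),
                       simplify = FALSE)
    for (u in units) {
      starts <- sample.int(length - unit_length, copies_per_unit, replace = TRUE)
      flip <- runif(copies_per_unit) < 0.5
      for (i in seq_len(copies_per_unit)) {
        cp <- if (flip[i]) rev(3L - u) else u
        x[starts[i]:(starts[i] + unit_length - 1L)] <- cp
      }
    }
    tl <- sample(tract_length[1]:tract_length[2], n_tracts, replace = TRUE)
    ts <- sample.int(length - max(tract_length), n_tracts, replace = TRUE)
    tb <- sample(c(0L, 3L), n_tracts, replace = TRUE) # poly-A or poly-T
    for (i in seq_len(n_tracts)) {
      x[ts[i]:(ts[i] + tl[i] - 1L)] <- tb[i]
    }
    x
  })
  tibble(name = name, seq = .codes_to_string(codes))
}

.check_per_window <- function(records) {
  if (nrow(records) == 0L) abort("`records` is empty.")
  if (dplyr::n_distinct(records$seqname) > 1L) {
    abort("Adjacency statistics are defined per sequence; pass one sequence's records.")
  }
  records[order(records$window_index), ]
}

#' Empirical adjacency probability of a minimizer stream
#'
#' The fraction of adjacent window pairs selecting the same occurrence
#' (identical `fwd_start` and `strand`), whose limit for random sequences is
#' `1 - 2/(w + 1)` as the window length grows. Equality of the selected k-mer
#' value only (a weaker event) is reported alongside as a diagnostic.
#'
#' @param records Per-window minimizer records (from [stream_minimizers()]
#'   with `collapse = FALSE`); a single sequence.
#' @return A one-row tibble with `n_pairs`, `p_same_occurrence`,
#'   `p_same_value`. A warning is attached below 10^4 pairs.
#' @export
adjacency_probability <- function(records) {
  records <- .check_per_window(records)
  adj <- diff(records$window_index) == 1L
  if (sum(adj) < 1e4) {
    warn("Fewer than 10^4 adjacent window pairs; the estimate may be unstable.")
  }
  n <- nrow(records)
  same_occ <- records$fwd_start[-1L] == records$fwd_start[-n] &
    records$strand[-1L] == records$strand[-n]
  same_val <- records$kmer[-1L] == records$kmer[-n]
  tibble(
    n_pairs = sum(adj),
    p_same_occurrence = mean(same_occ[adj]),
    p_same_value = mean(same_val[adj])
  )
}

#' Rate of delta sign changes between adjacent windows
#'
#' The empirical `P(delta_n * delta_(n+1) < 0)`, which controls the density
#' excess of the refined scheme over the standard one and vanishes as the
#' window length grows on random sequences.
#'
#' @inheritParams adjacency_probability
#' @return The fraction of adjacent window pairs with opposite delta signs.
#' @export
delta_sign_change_rate <- function(records) {
  records <- .check_per_window(records)
  adj <- diff(records$window_index) == 1L
  n <- nrow(records)
  flip <- (records$delta[-1L] * records$delta[-n]) < 0
  mean(flip[adj])
}

#' Compare densities of the standard, refined, and solo-skip schemes
#'
#' Streams the same sequence three ways and reports each scheme's density.
#' The refined density exceeds the standard one by at most the delta
#' sign-change rate, and solo skipping can only remove selections.
#'
#' @param seqs A sequence tibble (columns `name`, `seq`) or character vector.
#' @param k,w Window geometry (`w + k - 1` must be odd).
#' @param scheme An [order_scheme()].
#' @return A tibble with columns `mode`, `n_selected`, `density`.
#' @export
density_comparison <- function(seqs, k, w,
                               scheme = order_scheme("lexicographic", k)) {
  runs <- list(
    standard = list(mode = "standard", heuristic = "none"),
    refined = list(mode = "refined", heuristic = "none"),
    refined_solo_skip = list(mode = "refined", heuristic = "solo_skip")
  )
  purrr::imap(runs, function(r, nm) {
    rec <- sketch_minimizers(seqs, k = k, w = w, scheme = scheme,
                             mode = r$mode, heuristic = r$heuristic,
                             quiet = TRUE)
    tibble(
      mode = nm,
      n_selected = nrow(.distinct_occurrences(rec)),
      density = minimizer_density(rec, attr(rec, "seq_length"))
    )
  }) |>
    dplyr::bind_rows()
}

#' Analytic speedup of the refined over the standard minimizer
#'
#' Operation-count model for one window under a rolling order hash: the
#' standard scheme ranks the `2w` k-mers of both strands,
#' `o_std = 8 o1 + o2 + 2 w (3 o1 + o_R + o3)`, while the refined scheme pays
#' a constant delta overhead and ranks `w` k-mers,
#' `o_rfd = 10 o1 + 2 o2 + o3 + w (3 o1 + o_R + o3)`. With the default costs
#' (`o1 = 1`, `o2 = 3`, `o3 = 10`) the ratio `o_std / o_rfd` equals
#' `2 - 41 / (26 + w (13 + o_R))`: minimized at `37/39 ~ 0.949` for
#' `(w = 1, o_R = 0)`, increasing in both `w` and `o_R`, and bounded above
#' by 2.
#'
#' @param w Number of k-mers per window (vectorized).
#' @param o_R Cost of the order hash in cycles (vectorized; 0 for
#'   lexicographic).
#' @param o1,o2,o3 Costs of arithmetic/logic ops, an L1 cache read, and a
#'   branch, in cycles.
#' @return A tibble over the `(w, o_R)` grid with columns `w`, `o_R`,
#'   `cost_standard`, `cost_refined`, `speedup`.
#' @examples
#' speedup_model(w = c(1, 10), o_R = 0)
#' @export
speedup_model <- function(w, o_R = 0, o1 = 1, o2 = 3, o3 = 10) {
  stopifnot(all(w >= 1), all(o_R >= 0), o1 >= 0, o2 >= 0, o3 >= 0)
  grid <- tidyr::expand_grid(w = as.numeric(w), o_R = as.numeric(o_R))
  per_kmer <- 3 * o1 + grid$o_R + o3
  grid |>
    dplyr::mutate(
      cost_standard = 8 * o1 + o2 + 2 * .data$w * per_kmer,
      cost_refined = 10 * o1 + 2 * o2 + o3 + .data$w * per_kmer,
      speedup = .data$cost_standard / .data$cost_refined
    )
}
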