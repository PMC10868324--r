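toy_records <- function(starts, strands, kmers, seqname = "s") {
  tibble::tibble(
    seqname = seqname, window_index = seq_along(starts) - 1L,
    fwd_start = as.integer(starts), end = as.integer(starts + nchar(kmers)),
    kmer = kmers, rank = encode_kmer(kmers), strand = strands,
    delta = 1L, mode = "standard"
  )
}

test_that("density is distinct occurrences over sequence length", {
  rec <- toy_records(c(0, 10), c("+", "+"), c("ACGTA", "TTTTT"))
  expect_identical(minimizer_density(rec, 100), 0.02)
  # repeated occurrence counts once
  rec2 <- toy_records(c(0, 0, 10), c("+", "+", "-"),
                      c("ACGTA", "ACGTA", "TTTTT"))
  expect_identical(minimizer_density(rec2, 100), 0.02)
  expect_warning(z <- minimizer_density(rec[0, ], 100), "Empty")
  expect_identical(z, 0)

  # homopolymer: every one of the 90 windows selects a fresh tied occurrence
  fx <- make_fixture("all_A")
  rec <- stream_minimizers(fx$sequence, 5, 7)
  expect_identical(minimizer_density(rec, 100), 0.9)
})

test_that("frequency tables count distinct selections and merge additively", {
  fx <- make_fixture("table2")
  rec <- stream_minimizers(fx$sequence, 5, 7, mode = "refined")
  ft <- frequency_table(rec, 25)
  expect_setequal(ft$kmer, c("ACTTT", "CTTTG", "GGTGT", "GGTAA", "AAATG"))
  expect_true(all(ft$n == 1L))
  expect_equal(ft$v, ft$n / 25)
  expect_equal(ft$v_per_mb, ft$v * 1e6)

  s1 <- simulate_sequence(400, seed = 81, name = "s1")
  s2 <- simulate_sequence(400, seed = 82, name = "s2")
  both <- sketch_minimizers(dplyr::bind_rows(s1, s2), 5, 7, quiet = TRUE)
  f_both <- frequency_table(both, 800)
  f_sep <- dplyr::bind_rows(
    frequency_table(sketch_minimizers(s1, 5, 7, quiet = TRUE), 800),
    frequency_table(sketch_minimizers(s2, 5, 7, quiet = TRUE), 800)
  ) |>
    dplyr::count(kmer, wt = n, name = "n")
  expect_identical(
    dplyr::arrange(f_both[, c("kmer", "n")], kmer),
    dplyr::arrange(f_sep, kmer)
  )
})

test_that("frequency percentiles interpolate order statistics", {
  expect_identical(freq_percentiles(c(1, 2, 3, 4), probs = 0.5)$value, 2.5)
  expect_true(all(freq_percentiles(rep(7, 10))$value == 7))
  expect_error(freq_percentiles(numeric(0)), "nonempty")
  set.seed(83)
  for (i in 1:50) {
    x <- runif(sample(2:40, 1), 0, 100)
    p <- runif(3, 0.01, 0.99)
    expect_equal(freq_percentiles(x, p)$value,
                 vapply(p, function(pp) oracle_quantile(x, pp), numeric(1)))
  }
})

test_that("KL divergence against uniform behaves as a divergence", {
  expect_equal(kl_divergence(rep(3L, 64), k = 3), 0)
  expect_equal(kl_divergence(5L, k = 2), log(16))
  set.seed(84)
  for (i in 1:20) {
    cnt <- rpois(30, 4)
    cnt <- cnt[cnt > 0]
    if (length(cnt) == 0) next
    expect_gte(kl_divergence(cnt, k = 4), 0)
    expect_equal(kl_divergence(cnt, k = 4), kl_divergence(sample(cnt), k = 4))
  }
  expect_error(kl_divergence(integer(0), 3), "at least one")
})

test_that("expected hits is the count-weighted mean occurrence", {
  expect_equal(e_hits(rep(1L, 9)), 1)
  expect_equal(e_hits(4L), 4)
  expect_equal(e_hits(c(3L, 1L)), 2.5)
  expect_equal(e_hits(rep(6L, 11)), 6) # equal counts c give exactly c
  expect_error(e_hits(integer(0)), "at least one")
})

test_that("expected occurrence per k-mer type follows 2|S|/((w+1)4^k)", {
  # genome-scale 20-mers: essentially zero occurrences per type
  expect_lt(expected_occurrence(3e9, window_length = 30, k = 20), 1e-2)
  # algebraic identity: |S| = 4^k (w+1)/2 gives exactly 1
  k <- 6; w <- 9
  expect_equal(expected_occurrence(4^k * (w + 1) / 2, w + k - 1, k), 1)
  # decreasing k by 1 multiplies by 4 at fixed w and |S|
  expect_equal(expected_occurrence(1e6, 15 + 7, 7) /
                 expected_occurrence(1e6, 15 + 8, 8), 4)
  # observed-density form
  expect_equal(expected_occurrence(100, 11, 5, density = 0.2),
               0.2 * 100 / 4^5)
})

test_that("running summary reproduces the worked-example medians and ranges", {
  fx <- make_fixture("table2")
  exp <- fx$expected
  rfd <- stream_minimizers(fx$sequence, 5, 7, mode = "refined",
                           collapse = FALSE)
  std <- stream_minimizers(fx$sequence, 5, 7, mode = "standard",
                           collapse = FALSE)
  rs <- running_summary(rfd$rank)
  expect_identical(rs$median, exp$rfd_q2)
  expect_identical(rs$range, exp$rfd_range)
  ss <- running_summary(std$rank)
  expect_identical(ss$median, exp$std_q2)
  expect_identical(ss$range, exp$std_range)
  cs <- running_summary(rep(42, 5))
  expect_true(all(cs$median == 42) && all(cs$range == 0))
})

test_that("minimizer_stats bundles the statistics coherently", {
  rec <- sketch_minimizers(simulate_sequence(20000, seed = 85), 5, 11,
                           mode = "refined", quiet = TRUE)
  st <- minimizer_stats(rec, window_length = 15)
  expect_s3_class(st, "minimizer_stats")
  expect_identical(st$n_selected, nrow(dplyr::distinct(
    rec, seqname, fwd_start, strand)))
  expect_equal(sum(tidy(st)$n), st$n_selected) # conservation
  expect_equal(st$e_occ_observed, st$density * 20000 / 4^5)
  g <- glance(st)
  expect_identical(nrow(g), 1L)
  expect_true(all(c("density", "kl_divergence", "e_hits", "p25", "p95")
                  %in% names(g)))
  expect_s3_class(autoplot(st, standard = st), "ggplot")
})
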