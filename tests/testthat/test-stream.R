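test_that("streaming reproduces the packaged worked example per window", {
  fx <- make_fixture("table2")
  exp <- fx$expected
  rfd <- stream_minimizers(fx$sequence, k = 5, w = 7, mode = "refined",
                           collapse = FALSE)
  std <- stream_minimizers(fx$sequence, k = 5, w = 7, mode = "standard",
                           collapse = FALSE)
  expect_identical(rfd$window_index, exp$n - 1L)
  expect_identical(rfd$delta, exp$delta_window)
  expect_identical(-rfd$delta, exp$delta_revcomp)
  expect_identical(rfd$kmer, exp$rfd_kmer)
  expect_identical(rfd$rank, exp$rfd_rank)
  expect_identical(std$kmer, exp$std_kmer)
  expect_identical(std$rank, exp$std_rank)
  # the streamed windows themselves match the printed ones
  wins <- substring(fx$sequence$seq, exp$n, exp$n + 10L)
  expect_identical(wins, exp$window)
  expect_identical(reverse_complement(wins), exp$revcomp)
})

test_that("a homopolymer selects one k-mer value but a fresh tie every window", {
  # With leftmost tie-breaking the previous selection exits the window at each
  # slide, so poly-A yields one occurrence per window — the poly-X pathology
  # that motivates tie-skipping heuristics.
  fx <- make_fixture("all_A")
  std <- stream_minimizers(fx$sequence, k = 5, w = 7, mode = "standard")
  expect_identical(nrow(std), 90L)
  expect_true(all(std$kmer == "AAAAA") && all(std$strand == "+"))
  expect_identical(std$fwd_start, std$window_index) # leftmost candidate
  rfd <- stream_minimizers(fx$sequence, k = 5, w = 7, mode = "refined")
  expect_true(all(rfd$kmer == "TTTTT") && all(rfd$strand == "-"))
  expect_identical(nrow(dplyr::distinct(std, kmer)), 1L)
})

test_that("collapsing keeps the earliest window of each occurrence run", {
  s <- simulate_sequence(3000, seed = 55)$seq
  per <- stream_minimizers(s, 5, 7, mode = "refined", collapse = FALSE,
                           quiet = TRUE)
  col <- stream_minimizers(s, 5, 7, mode = "refined", collapse = TRUE,
                           quiet = TRUE)
  occ <- paste(per$fwd_start, per$strand)
  keep <- c(TRUE, occ[-1] != occ[-length(occ)])
  expect_identical(col$window_index, per$window_index[keep])
  expect_identical(col$fwd_start, per$fwd_start[keep])
  expect_identical(col$kmer, per$kmer[keep])
})

test_that("streams equal the naive per-window oracle on random sequences", {
  s <- simulate_sequence(2000, seed = 57)$seq
  for (mode in c("standard", "refined")) {
    for (kind in c("lexicographic", "random")) {
      sch <- order_scheme(kind, 5, seed = 4)
      got <- stream_minimizers(s, 5, 7, scheme = sch, mode = mode,
                               collapse = FALSE, quiet = TRUE)
      exp <- oracle_stream(s, 5, 7, sch, mode)
      expect_identical(got$window_index, exp$window_index)
      expect_identical(got$fwd_start, as.integer(exp$fwd_start))
      expect_identical(got$rank, exp$rank)
      expect_identical(got$strand, exp$strand)
      expect_identical(got$kmer, exp$kmer)
      expect_identical(got$delta, as.integer(exp$delta))
    }
  }
})

test_that("windows overlapping N are skipped and streaming resumes", {
  s <- paste0(simulate_sequence(300, seed = 58)$seq, "N",
              simulate_sequence(300, seed = 59)$seq)
  expect_message(
    got <- stream_minimizers(s, 5, 7, mode = "refined", collapse = FALSE),
    "skipped 11 window"
  )
  exp <- oracle_stream(s, 5, 7, order_scheme("lexicographic", 5), "refined")
  expect_identical(got$window_index, exp$window_index)
  expect_identical(got$rank, exp$rank)
  expect_identical(got$kmer, exp$kmer)
  # no window touches the N
  expect_false(any(got$window_index %in% (300 - 10):300))
})

test_that("short sequences yield an empty record set with a warning", {
  expect_warning(rec <- stream_minimizers("ACGTACGTAC", 5, 7), "shorter")
  expect_identical(nrow(rec), 0L)
  expect_named(rec, c("seqname", "window_index", "fwd_start", "end", "kmer",
                      "rank", "strand", "delta", "mode"))
})

test_that("refined mode rejects even window lengths", {
  expect_error(stream_minimizers("ACGTACGTACGT", 5, 6, mode = "refined"),
               "odd")
  expect_error(stream_minimizers("ACGTACGTACGT", 5, 6, heuristic = "solo_skip"),
               "odd")
})

test_that("solo-window mask follows the sign-of-neighbours rule", {
  expect_identical(solo_window_mask(c(-1, 1, -1)), c(TRUE, FALSE, TRUE))
  expect_identical(solo_window_mask(c(-1, 1, 1)), c(TRUE, TRUE, TRUE))
  expect_identical(solo_window_mask(c(3, 5, 7, 1)), rep(TRUE, 4))
  expect_identical(solo_window_mask(c(-1, 1)), c(TRUE, TRUE)) # boundaries kept
  expect_error(solo_window_mask(c(-1, 0, 1)), "Zero delta")
})

test_that("solo skipping drops exactly the solo windows before collapsing", {
  s <- simulate_sequence(4000, seed = 61)$seq
  per <- stream_minimizers(s, 4, 8, mode = "refined", collapse = FALSE,
                           quiet = TRUE)
  skp <- stream_minimizers(s, 4, 8, mode = "refined", heuristic = "solo_skip",
                           collapse = FALSE, quiet = TRUE)
  keep <- solo_window_mask(per$delta)
  expect_identical(skp$window_index, per$window_index[keep])
  expect_identical(skp$rank, per$rank[keep])
  # subset property on distinct occurrences, collapsed
  col <- stream_minimizers(s, 4, 8, mode = "refined", quiet = TRUE)
  col_skp <- stream_minimizers(s, 4, 8, mode = "refined",
                               heuristic = "solo_skip", quiet = TRUE)
  expect_true(all(occurrence_keys(col_skp) %in% occurrence_keys(col)))
})

test_that("sketching a sequence set binds records and tracks total length", {
  seqs <- tibble::tibble(
    name = c("a", "b"),
    seq = c(simulate_sequence(200, seed = 62)$seq,
            simulate_sequence(150, seed = 63)$seq)
  )
  rec <- sketch_minimizers(seqs, k = 5, w = 7, mode = "refined", quiet = TRUE)
  expect_identical(attr(rec, "seq_length"), 350L)
  expect_setequal(unique(rec$seqname), c("a", "b"))
  one <- stream_minimizers(seqs$seq[2], 5, 7, mode = "refined",
                           seqname = "b", quiet = TRUE)
  expect_identical(rec[rec$seqname == "b", ], one, ignore_attr = TRUE)
})
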