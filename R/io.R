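# FASTA input, selection output (TSV / BED), packaged fixtures, and the flat
# run configuration used by the command-line interface.

#' Read DNA sequences from a FASTA file
#'
#' Streams a (possibly gzipped) multi-record FASTA via Biostrings, uppercases
#' the sequences, and maps any IUPAC ambiguity code other than `A/C/G/T` to
#' `N`. Record names are truncated at the first whitespace, the usual
#' identifier convention.
#'
#' @param path Path to a FASTA or FASTA.gz file.
#' @return A tibble with columns `name`, `seq`, `width`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: ", path))
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) {
      abort(paste0("Malformed FASTA ", sQuote(path), ": ", conditionMessage(e)))
    }
  )
  if (length(ss) == 0L) abort(paste0("No records in FASTA file: ", path))
  seqs <- unname(gsub("[^ACGT]", "N", toupper(as.character(ss))))
  tibble(
    name = sub("\\s.*$", "", names(ss)),
    seq = seqs,
    width = nchar(seqs)
  )
}

#' Write sequences to a FASTA file
#'
#' @param seqs A tibble with columns `name`, `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(setNames(seqs$seq, seqs$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write minimizer selections to TSV or BED
#'
#' TSV columns: `seqname`, `fwd_start` (0-based), `end` (half-open), `kmer`
#' (oriented as selected), `rank`, `strand`, `window_index`, `mode`. BED6
#' output uses `name = kmer` and `score = min(rank, 1000)` (the clamp is noted
#' in a leading comment line, as BED scores are capped at 1000). Rows are
#' ordered by `(seqname, fwd_start, window_index)`.
#'
#' @param records A tibble of minimizer records.
#' @param path Output path.
#' @param format `"tsv"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_selections <- function(records, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  records <- dplyr::arrange(records, .data$seqname, .data$fwd_start,
                            .data$window_index)
  if (format == "tsv") {
    out <- records[, c("seqname", "fwd_start", "end", "kmer", "rank",
                       "strand", "window_index", "mode")]
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("# BED6; score = min(rank, 1000)", con)
    if (nrow(records) > 0L) {
      bed <- data.frame(
        chrom = records$seqname,
        start = records$fwd_start,
        end = records$end,
        name = records$kmer,
        score = pmin(records$rank, 1000),
        strand = records$strand
      )
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a selections TSV back into a record tibble
#'
#' Inverse of [write_selections()] for the TSV format.
#'
#' @param path Path to a TSV written by [write_selections()].
#' @return A tibble of minimizer records.
#' @export
read_selections <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = c(
                            seqname = "character", fwd_start = "integer",
                            end = "integer", kmer = "character",
                            rank = "numeric", strand = "character",
                            window_index = "integer", mode = "character"
                          ))
  as_tibble(df)[, c("seqname", "window_index", "fwd_start", "end", "kmer",
                    "rank", "strand", "mode")]
}

# The 25-base worked-example sequence (streamed strand) and its 15 printed
# windows with per-window delta, standard/refined selections, and the running
# median / range of the rank traces.
.TABLE2_SEQ <- "AGCTTACTTTGGTGTTTGGTAAATG"

.table2_expected <- function() {
  tibble(
    n = 1:15,
    window = c(
      "AGCTTACTTTG", "GCTTACTTTGG", "CTTACTTTGGT", "TTACTTTGGTG",
      "TACTTTGGTGT", "ACTTTGGTGTT", "CTTTGGTGTTT", "TTTGGTGTTTG",
      "TTGGTGTTTGG", "TGGTGTTTGGT", "GGTGTTTGGTA", "GTGTTTGGTAA",
      "TGTTTGGTAAA", "GTTTGGTAAAT", "TTTGGTAAATG"
    ),
    revcomp = c(
      "CAAAGTAAGCT", "CCAAAGTAAGC", "ACCAAAGTAAG", "CACCAAAGTAA",
      "ACACCAAAGTA", "AACACCAAAGT", "AAACACCAAAG", "CAAACACCAAA",
      "CCAAACACCAA", "ACCAAACACCA", "TACCAAACACC", "TTACCAAACAC",
      "TTTACCAAACA", "ATTTACCAAAC", "CATTTACCAAA"
    ),
    delta_window = c(3L, 5L, 5L, 7L, 7L, 7L, 9L, 11L, 11L, 11L, 9L, 7L, 5L,
                     5L, 5L),
    delta_revcomp = c(-3L, -5L, -5L, -7L, -7L, -7L, -9L, -11L, -11L, -11L,
                      -9L, -7L, -5L, -5L, -5L),
    std_kmer = c(rep("AAAGT", 6), rep("AAACA", 7), "ACCAA", "AAATG"),
    rfd_kmer = c(rep("ACTTT", 6), "CTTTG", rep("GGTGT", 4), rep("GGTAA", 3),
                 "AAATG"),
    std_rank = c(rep(11, 6), rep(4, 7), 80, 14),
    rfd_rank = c(rep(127, 6), 510, rep(699, 4), rep(688, 3), 14),
    std_q2 = c(rep(11, 12), 4, 11, 11),
    rfd_q2 = c(rep(127, 11), 510, 510, 688, 510),
    std_range = c(rep(0, 6), rep(7, 7), 76, 76),
    rfd_range = c(rep(0, 6), 383, rep(572, 7), 685)
  )
}

#' Packaged test fixtures
#'
#' Three small inputs used throughout the examples and tests:
#' \describe{
#'   \item{`table2`}{the 25-base worked example whose 15 windows (`|s| = 11`,
#'     `k = 5`, lexicographic order) exercise every part of the refined
#'     scheme; `expected` carries the full per-window reference values
#'     (deltas, standard/refined k-mers and ranks, running median and range).}
#'   \item{`all_A`}{a homopolymer of 100 A's — a single selected k-mer value,
#'     but (under leftmost tie-breaking) one fresh tied occurrence per window:
#'     the poly-X regime where tie-skipping heuristics earn their keep.}
#'   \item{`random_small`}{a fixed-seed 200-base i.i.d. sequence with one
#'     ambiguous base, byte-identical across runs.}
#' }
#'
#' @param name One of `"table2"`, `"all_A"`, `"random_small"`.
#' @return A list with elements `sequence` (tibble: `name`, `seq`), `params`
#'   (list with `k`, `w`, `window_length` where applicable), and for `table2`
#'   an `expected` tibble.
#' @export
make_fixture <- function(name = c("table2", "all_A", "random_small")) {
  name <- match.arg(name)
  switch(name,
    table2 = list(
      sequence = tibble(name = "table2", seq = .TABLE2_SEQ),
      params = list(k = 5L, w = 7L, window_length = 11L),
      expected = .table2_expected()
    ),
    all_A = list(
      sequence = tibble(name = "all_A", seq = strrep("A", 100L)),
      params = list(k = 5L, w = 7L, window_length = 11L)
    ),
    random_small = {
      s <- simulate_sequence(200, p_ac = 0.5, seed = 20240125,
                             name = "random_small")
      s$seq <- paste0(substr(s$seq, 1, 100), "N", substr(s$seq, 102, 200))
      list(sequence = s, params = list(k = 5L, w = 7L, window_length = 11L))
    }
  )
}

#' Assemble and validate a run configuration
#'
#' A flat, fully serializable description of a sketching run, so any result
#' can be reproduced from its recorded configuration and seed.
#'
#' @param fasta Input FASTA path.
#' @param k,w Window geometry.
#' @param order `"lexicographic"` or `"random"`.
#' @param seed Seed for the random order.
#' @param mode `"standard"` or `"refined"`.
#' @param heuristic `"none"` or `"solo_skip"`.
#' @param collapse Collapse consecutive same-occurrence windows.
#' @param out Output path (optional).
#' @param format `"tsv"` or `"bed"`.
#' @param log_level `"quiet"` or `"info"`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(fasta, k, w, order = "lexicographic", seed = 0L,
                       mode = "standard", heuristic = "none", collapse = TRUE,
                       out = NULL, format = "tsv", log_level = "info") {
  k <- as.integer(k)
  w <- as.integer(w)
  stopifnot(k >= 1, w >= 1)
  order <- match.arg(order, c("lexicographic", "random"))
  mode <- match.arg(mode, c("standard", "refined"))
  heuristic <- match.arg(heuristic, c("none", "solo_skip"))
  format <- match.arg(format, c("tsv", "bed"))
  log_level <- match.arg(log_level, c("quiet", "info"))
  if (mode == "refined" && (w + k - 1L) %% 2L == 0L) {
    abort("Refined mode requires an odd window length w + k - 1.")
  }
  structure(
    list(fasta = fasta, k = k, w = w, order = order, seed = as.integer(seed),
         mode = mode, heuristic = heuristic, collapse = isTRUE(collapse),
         out = out, format = format, log_level = log_level),
    class = "run_config"
  )
}

#' Write a run configuration as flat key=value lines
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  kv <- vapply(names(config), function(nm) {
    v <- config[[nm]]
    paste0(nm, "=", if (is.null(v)) "" else as.character(v))
  }, character(1))
  writeLines(kv, path)
  invisible(path)
}

#' Read a flat key=value run configuration
#'
#' @param path Path written by [write_run_config()].
#' @return A validated [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(
    lapply(kv, function(x) paste(x[-1L], collapse = "=")),
    vapply(kv, `[[`, character(1), 1L)
  )
  num <- function(x) if (is.null(x) || x == "") NULL else as.integer(x)
  chr <- function(x, default) if (is.null(x) || x == "") default else x
  run_config(
    fasta = chr(vals$fasta, NULL),
    k = num(vals$k), w = num(vals$w),
    order = chr(vals$order, "lexicographic"),
    seed = if (is.null(num(vals$seed))) 0L else num(vals$seed),
    mode = chr(vals$mode, "standard"),
    heuristic = chr(vals$heuristic, "none"),
    collapse = !identical(tolower(chr(vals$collapse, "true")), "false"),
    out = chr(vals$out, NULL),
    format = chr(vals$format, "tsv"),
    log_level = chr(vals$log_level, "info")
  )
}
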