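# Total orders on k-mers: the lexicographic 2-bit code and a seeded random
# bijection built from invertible mixing rounds on the 2k-bit code.

# All overlapping k-mer codes of a code vector (no NA allowed), as the
# polynomial sum(4^(k-1-j) * code[i+j]). Vectorized: k passes over the vector.
.kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  kc <- numeric(n - k + 1L)
  for (j in seq_len(k)) {
    kc <- kc * 4 + codes[j:(n - k + j)]
  }
  kc
}

# Reverse-complement k-mer codes at every forward offset: the code of the
# reverse complement of seq[i..i+k-1], i.e. sum(4^(j) * (3 - code[i+j])).
.rc_kmer_codes <- function(codes, k) {
  n <- length(codes)
  if (n < k) return(numeric(0))
  kc <- numeric(n - k + 1L)
  p <- 1
  for (j in seq_len(k)) {
    kc <- kc + (3 - codes[j:(n - k + j)]) * p
    p <- p * 4
  }
  kc
}

#' Lexicographic rank of k-mers
#'
#' Encodes k-mers as `sum_i 4^i * a_i` with `a_i = 0, 1, 2, 3` for A, C, G, T
#' and the rightmost character at `i = 0` — a bijection from the `4^k` k-mers
#' onto `[0, 4^k)`. Exact for `k <= 26` (the code must stay below 2^53).
#'
#' @param kmer Character vector of k-mers over `{A,C,G,T}` (N is not encodable).
#' @return Numeric vector of ranks.
#' @examples
#' encode_kmer("AAAGT") # 11
#' @export
encode_kmer <- function(kmer) {
  kmer <- normalize_sequence(kmer)
  k <- nchar(kmer)
  if (any(k > 26L)) abort("k-mers longer than 26 bases overflow the exact rank.")
  vapply(kmer, function(s) {
    codes <- .base_codes(s)
    if (anyNA(codes)) {
      abort("Cannot encode a k-mer containing ambiguous bases (N).")
    }
    .kmer_codes(codes, length(codes))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Decode a lexicographic rank back to its k-mer
#'
#' Inverse of [encode_kmer()]: `encode_kmer(decode_kmer(r, k)) == r` for all
#' `0 <= r < 4^k`.
#'
#' @param rank Numeric vector of ranks in `[0, 4^k)`.
#' @param k k-mer length.
#' @return Character vector of k-mers.
#' @examples
#' decode_kmer(127, 5) # "ACTTT"
#' @export
decode_kmer <- function(rank, k) {
  stopifnot(k >= 1, k == as.integer(k))
  if (any(rank < 0 | rank >= 4^k | rank != floor(rank))) {
    abort("`rank` must be an integer in [0, 4^k).")
  }
  bases <- c("A", "C", "G", "T")
  digits <- matrix("", nrow = length(rank), ncol = k)
  r <- rank
  for (j in k:1) {
    digits[, j] <- bases[(r %% 4) + 1]
    r <- r %/% 4
  }
  apply(digits, 1L, paste, collapse = "")
}

#' Construct a total order on k-mers
#'
#' An order scheme is an injective rank function on the `4^k` k-mers that
#' induces minimizer selection. Two kinds are provided:
#' \describe{
#'   \item{`lexicographic`}{the 2-bit positional code of [encode_kmer()].}
#'   \item{`random`}{a seeded bijection on `[0, 4^k)` built from rounds of
#'     odd-constant multiplication modulo `4^k` followed by an xor of a right
#'     shift — each round invertible, so the composition is a permutation.
#'     Available for `k <= 13` (products must stay exact in doubles).}
#' }
#'
#' @param kind `"lexicographic"` or `"random"`.
#' @param k k-mer length.
#' @param seed Non-negative integer seed (random kind only).
#' @return An object of class `order_scheme`.
#' @examples
#' sch <- order_scheme("random", k = 5, seed = 42)
#' kmer_rank("AAAGT", sch)
#' @export
order_scheme <- function(kind = c("lexicographic", "random"), k, seed = 0L) {
  kind <- match.arg(kind)
  stopifnot(k >= 1, k == as.integer(k))
  k <- as.integer(k)
  scheme <- list(kind = kind, k = k, seed = NULL)
  if (kind == "random") {
    if (k > 13L) {
      abort("Random orders are limited to k <= 13 (exact 2k-bit mixing in doubles).")
    }
    if (length(seed) != 1L || is.na(seed) || seed < 0 || seed != floor(seed)) {
      abort("`seed` must be a single non-negative integer.")
    }
    scheme$seed <- as.integer(seed)
    bits <- 2L * k
    # Small exact LCG (Marsaglia constants fit in double arithmetic) used only
    # to derive the mixing constants; the global RNG is untouched.
    state <- (seed + 1) %% 2^32
    draw <- function() {
      state <<- (69069 * state + 1) %% 2^32
      state
    }
    n_rounds <- 3L
    cbits <- min(bits, 53L - bits)
    mult <- numeric(n_rounds)
    shift <- integer(n_rounds)
    for (r in seq_len(n_rounds)) {
      mult[r] <- (draw() %% 2^(cbits - 1)) * 2 + 1 # odd, < 2^cbits
      shift[r] <- if (bits > 1L) 1L + draw() %% (bits - 1L) else 1L
    }
    scheme$mult <- mult
    scheme$shift <- shift
  } else if (k > 26L) {
    abort("Lexicographic orders are limited to k <= 26 (exact codes in doubles).")
  }
  structure(scheme, class = "order_scheme")
}

#' @export
print.order_scheme <- function(x, ...) {
  cat("<order_scheme>", x$kind, " k =", x$k)
  if (!is.null(x$seed)) cat(" seed =", x$seed)
  cat("\n")
  invisible(x)
}

# Apply the scheme's rank function to lexicographic codes (numeric vector).
.rank_codes <- function(codes, scheme) {
  if (scheme$kind == "lexicographic") {
    return(codes)
  }
  m <- 4^scheme$k
  x <- codes
  for (r in seq_along(scheme$mult)) {
    x <- (x * scheme$mult[r]) %% m
    x <- as.numeric(bitwXor(as.integer(x), as.integer(x %/% 2^scheme$shift[r])))
  }
  x
}

#' Rank k-mers under an order scheme
#'
#' Applies the scheme's injective rank function. For the random kind the result
#' is a seeded permutation of the lexicographic codes; deterministic for a
#' fixed `(kind, k, seed)`.
#'
#' @param kmer Character vector of k-mers of length `scheme$k`.
#' @param scheme An [order_scheme()].
#' @return Numeric vector of ranks in `[0, 4^k)`.
#' @export
kmer_rank <- function(kmer, scheme) {
  if (!inherits(scheme, "order_scheme")) abort("`scheme` must be an `order_scheme`.")
  if (any(nchar(kmer) != scheme$k)) {
    abort(paste0("All k-mers must have length k = ", scheme$k, "."))
  }
  .rank_codes(encode_kmer(kmer), scheme)
}
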