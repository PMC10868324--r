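---
title: "Refined canonical minimizers: model, conventions, and study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refined canonical minimizers: model, conventions, and study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltamin)
```

## The selection model

A minimizer scheme `(w, k, <)` slides a window of `w` consecutive k-mers
(window length `|s| = w + k - 1` bases) one base at a time and selects the
k-mer that is minimal under a total order `<`, realized here as an injective
rank function on the `4^k` k-mers. The *standard canonical* scheme takes the
minimum over the `2w` k-mers of both strands, so selection does not depend on
which strand of a genome was sequenced. Its weakness is structural: the
globally smallest k-mers are candidates on either strand of every window, so
they are selected over and over — for the lexicographic order these are the
A-rich k-mers, and the resulting frequency distribution has a heavy right
tail that hurts seeding and binning.

The *refined* scheme replaces the two-strand minimum with a strand decision.
For a window `s`, `delta(s) = pT + pG - pC - pA` (base occurrence counts).
Three structural facts make this a sound decision function:

1. **Parity.** If `|s|` is odd then `delta(s)` is odd, hence never zero.
   The package therefore rejects refined-mode geometries with even
   `w + k - 1`.
2. **Antisymmetry.** `delta(revcomp(s)) = -delta(s)`, so "scan the strand
   with positive delta" names the same physical strand no matter which
   orientation of the window you hold: `h_r(s) = h_r(revcomp(s))`
   (strand symmetry).
3. **Rolling.** Sliding the window one base changes delta by `+2`, `0`, or
   `-2` depending only on whether the outgoing and incoming bases fall in
   `{A,C}` or `{G,T}`, so the decision costs O(1) per window
   (`delta_update()`), and a stream recomputes nothing.

Because the refined minimum is taken over a subset of the standard
candidates, `h_s(s) <= h_r(s)` for every window and every total order
(dominance): the refined scheme is mechanically less biased toward the
bottom of the order. The price is density: when consecutive windows disagree
on the strand (`delta_n * delta_(n+1) < 0`), the refined scheme switches
candidate sets and tends to emit an extra occurrence. The probability of a
sign flip requires `|delta| = 1` and decays like a central binomial term as
`|s|` grows, so the refined density converges to the standard one from
above. On i.i.d. sequences with a random order both schemes approach the
classic `2/(w+1)` density and the `1 - 2/(w+1)` adjacent-window agreement
probability.

## Parameters that matter

* `k` (bases): k-mer length. Lexicographic ranks are exact for `k <= 26`;
  random orders for `k <= 13` (see below). Defaults are never implied; both
  `k` and `w` are always explicit.
* `w` (k-mers per window): controls density (`~2/(w+1)`) and, through
  `|s| = w + k - 1`, the flip rate of the strand decision. Refined mode
  requires odd `|s|`.
* `order_scheme(kind, k, seed)`: `lexicographic` is the positional base-4
  code (A,C,G,T = 0..3, rightmost position = 4^0). `random` composes three
  invertible rounds of odd-constant multiplication modulo `4^k` with an
  xor-right-shift, on the 2k-bit code; each round is a bijection, so the
  whole map is a seeded permutation of `[0, 4^k)`. Constants are derived
  from the seed by a small exact linear congruential generator, so schemes
  are reproducible across platforms and the global RNG is untouched. The
  `k <= 13` limit keeps every product below 2^53, i.e. exact in doubles.
* `mode`: `standard` or `refined`; `heuristic = "solo_skip"` additionally
  drops windows whose delta sign differs from both neighbours ("solo"
  windows) — these account for most strand flips, so skipping them trims
  the refined density premium while any non-solo selection remains
  recoverable from a neighbouring window. First and last windows of a run
  have one neighbour and are never classified solo.
* `collapse`: the distinct-occurrence convention. Consecutive windows that
  select the same `(fwd_start, strand)` contribute one record with the
  earliest window index; this is the counting under which `|X|/|S|` is the
  density with expectation `~2/(w+1)`. `collapse = FALSE` gives the
  per-window view used in the worked example.

## Conventions and numerical choices

* **Coordinates** are 0-based, half-open, always on the forward strand of
  the input sequence; a k-mer selected on the reverse complement is reported
  with its forward start and `strand = "-"`, and `kmer` holds the oriented
  (selected) sequence.
* **Tie-breaking**: minimum rank, then lowest forward start, then the `+`
  strand. Ties are real only for repeated k-mer content (ranks are
  injective); on homopolymers this rule selects a fresh occurrence every
  window — the known poly-X pathology of minimizer schemes. A tie-skipping
  heuristic for adjacent windows exists in the field but is deliberately not
  part of the core contract here.
* **Ambiguity (N)**: delta and the 2-bit encoding are undefined on N, so any
  window overlapping an N emits no record and invalidates the rolling state;
  streaming resumes at the next N-free window, and skipped-window counts are
  reported. Lowercase (soft-masked) bases are uppercased, not treated as N.
* **Running median**: the per-step median of a rank trace uses the
  upper-middle order statistic (`sorted[n %/% 2 + 1]`) for even prefixes.
  This is the convention under which the packaged worked example reproduces
  exactly; it matters only for even prefixes of short traces.
* **KL divergence**: the per-base frequency `v(x) = n(x)/|S|` sums to the
  density, not to 1, so the divergence is computed between probability
  distributions `p(x) = n(x)/|X|` and the uniform `u(x) = 1/4^k`, in nats,
  with `0 log 0 = 0`. Zero-count terms vanish, so summing over the support
  is exact for any `k`.
* **Percentiles** of the frequency variable `V` are taken over the distinct
  selected k-mer values (unweighted), scaled to occurrences per megabase,
  with linear interpolation between order statistics.
* **Extended operator**: `extended_delta()` generalizes delta to overlapping
  q-mer counts, one odd weight per complement pair `{r, revcomp(r)}` with
  the lexicographically greater member carrying the positive sign — the
  orientation under which `q = 1` with unit weights is exactly `delta()`.
  For even `q`, palindromic q-mers equal their own reverse complement,
  contribute identically zero, and carry no weight; for odd `q` there are
  exactly `4^q/2` pairs.

## What the simulators emulate

`simulate_sequence()` draws i.i.d. bases with `P{A,C} = p_ac` (split evenly
within the class) — exactly the composition model under which the limit
statements above are proved, with `E[delta]/|s| = 1 - 2 p_ac`.
`simulate_repetitive_sequence()` adds the two features of real genomes that
drive lexicographic repetitiveness: a library of dispersed repeat units
copied onto random positions of either strand (defaults: 10 units of 150 bp,
100 copies each, ~15% of a megabase) and short poly-A/poly-T tracts
(defaults: 1000 tracts of 10–30 bp). These defaults were chosen once as a
plausible repeat load for a mammalian-like megabase and are not tuned.

What the generators do **not** emulate: long-range GC structure, tandem
satellite arrays, sequencing error, and the scale of a full genome. Passing
the simulation-based tests therefore demonstrates the scheme's mathematical
properties and the direction of its repetitiveness improvement, not the
magnitude of its benefit on any particular genome — which grows with
sequence size, since the expected occurrences per k-mer type
`E(X,k) ~ 2|S| / ((w+1) 4^k)` must be appreciable before frequency
distributions separate.

## Study conditions used by the test suite

Problem sizes were chosen so the whole suite runs comfortably on one CPU:
strand symmetry and dominance on 10^4 random 11-base windows under the
lexicographic order and three random-order seeds; streaming versus a naive
per-window oracle on 10 kb sequences for all mode/order combinations;
order bijectivity exhaustively for `k <= 8`. Convergence experiments use
1 Mb i.i.d. sequences with 5 replicate seeds and 3-standard-error bands
(standard errors estimated across replicates): adjacency probability and
density against their closed forms at `w ∈ {5, 10, 20}` with `k = 12`, and
the refined-minus-standard density gap and sign-flip rate at
`|s| ∈ {21, 41, 81}`. The directional repetitiveness comparison uses one
repeat-structured megabase at `|s| = 15`, `k = 8` under the lexicographic
order.

## Known limitations

* The refined scheme targets canonical (double-strand) minimizers only;
  single-strand schemes (e.g. RNA) have no strand to decide.
* The operation-cost model (`speedup_model()`) is an analytic count under a
  fixed cost table (`o1 = 1`, `o2 = 3`, `o3 = 10` cycles, plus the order
  hash `o_R`); it predicts a speedup in `[0.949, 2)` but is not a wall-clock
  benchmark, and buffer-based implementations can wash out part of it.
* Homopolymer and low-complexity regions still produce dense, tied
  selections under any within-window tie rule; combining the refined
  operator with adjacent-window tie skipping is the practical remedy.
* Random orders are limited to `k <= 13` by exact double-precision
  arithmetic; lexicographic orders to `k <= 26`.

```{r example}
fx <- make_fixture("table2")
rfd <- stream_minimizers(fx$sequence, k = 5, w = 7, mode = "refined",
                         collapse = FALSE)
std <- stream_minimizers(fx$sequence, k = 5, w = 7, mode = "standard",
                         collapse = FALSE)
all(std$rank <= rfd$rank) # dominance on the worked example
tail(running_summary(rfd$rank), 1)
```
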