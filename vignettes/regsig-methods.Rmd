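---
title: "Models and methods behind regsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regsig)
```

`regsig` annotates transcription control signals — transcription factor
binding sites (TFBS), alternative sigma-factor promoters and intrinsic
terminators — in annotated bacterial genomes, and infers the transcription
units those signals control. This vignette documents the underlying
models, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data validation does and does not demonstrate.

## Binding-site model

A regulator's binding specificity is modelled as a position weight matrix
over the columns of a gapless site alignment. With `n` sites and a
per-base pseudocount `c` (default 0.5, a Laplace-style regulariser; at
typical collection sizes of 20–100 sites it barely moves the estimates but
keeps log-odds finite),

$$p(b, j) = \frac{\mathrm{count}(b, j) + c}{n + 4c},$$

where an `N` in the input contributes 1/4 of a count to each base — a
degenerate base is data of unknown identity, never an error. A window
`w = b_1..b_L` scores

$$S(w) = \sum_{j \notin \text{mask}} \log_2 \frac{p(b_j, j)}{q(b_j)}$$

in bits against the background `q` (default uniform; configurable, e.g.
for strongly AT-rich genomes). Masked columns — spacer positions between
the conserved boxes of a promoter, say — contribute nothing to scores or
to information content. An `N` at an unmasked position contributes the
`q`-weighted mean of the column's log-odds, i.e. exactly its expected
contribution.

Per-column information content uses the uniform-background definition
$IC_j = 2 + \sum_b p \log_2 p \in [0, 2]$, which is also the column height
of a sequence logo (letter heights are `p * IC_j`, `logo_matrix()`). A
small-sample correction of `3 / (2 ln(2) n)` bits per column can be
switched on in `information_content()`; it is off by default because the
uncorrected quantity is the logo convention and collection sizes differ
wildly between regulators, so the correction is better applied knowingly
than silently.

Scoring is ungapped by design. Short bacterial regulatory sites are
essentially fixed-width; profile HMMs with insert/delete states
(`nhmmer`-style) and PWM scanning perform near-identically on such
alignments, and the PWM form admits an *exact* null distribution (below),
which an HMM does not.

## Exact p-values

The p-value of a score threshold `t` is the probability that a random
L-mer drawn from `q` scores at least `t`. Because the per-column score is
a discrete 4-outcome variable and columns are independent under the null,
the full distribution of `S` is the convolution of L tiny distributions.
`score_pvalue()` computes it by dynamic programming after rounding each
log-odds value to a multiple of the granularity `g` (default 0.001 bits):
the accumulated rounding error on any word's score is at most `L g / 2`,
so the DP tail probability is bracketed by the exact tails at
`t ± L g / 2`. At motif scale (L ≤ 40, score spans of a few hundred bits)
the DP has at most a few hundred thousand bins and runs in milliseconds;
the test suite checks the bracket against exhaustive enumeration over all
`4^L` words for L ≤ 8. Words containing a zero-probability base (possible
at pseudocount 0) have score `-Inf`; their mass is tracked separately and
never reaches a finite threshold, and such windows are not emitted as
hits.

## Calibration

Each profile stores three cutoffs in bits, in the HMMER convention:
*trusted* = the lowest score among the known true sites, *noise* = the
highest score of a nonspecific hit, *gathering* = their arithmetic mean,
used as the default scanning threshold. `calibrate()` enforces none of the
canonical ordering: if noise reaches trusted it warns and stores the
values anyway, because real collections do contain weak true sites below
strong decoys and the cutoffs must remain representable. Without decoy
scores a provisional noise cutoff of `trusted - 0.5 |trusted|` is stored
and flagged, to be replaced once a genome scan supplies real nonspecific
scores.

One numerical caveat worth knowing: scores computed by `score_window()`
and by the vectorised genome scan can differ by ~1e-14 (different
summation order), so decoy sets should be selected by coordinates (does
the hit overlap a known site?) rather than by exact score comparison. The
worked examples and the optimisation loop both do this.

## Scanning and context filtering

`scan_genome()` always scans both strands (minus-strand hits are reported
in top-strand coordinates), keeps ties at the cutoff, and does not wrap
the origin of circular replicons — a simplification that loses at most one
site per replicon. Orientation handling is deliberately deferred to the
filter stage.

`filter_hits()` implements the context rules, classifying each hit with
precedence intragenic > converging-region > upstream-ok:

* *intragenic*: the hit intersects any gene/CDS (dropped by default,
  retainable for regulators known to bind within ORFs);
* *converging-region*: the hit lies between the facing 3' ends of two
  adjacent opposite-strand genes — downstream of both, where no promoter
  or activator site belongs;
* *upstream-ok*: the nearest same-strand gene start downstream of the hit
  lies within `[min_upstream, max_upstream]` (defaults 0–300 nt) of the
  hit's 3' edge — typical bacterial promoter/operator spacing;
* everything else is *wrong-orientation*.

The window bounds are stored per profile, since sigma-factor promoters
and, e.g., repressors tolerate different spacings. For palindromic motifs
the strand-symmetric double report is removed first: hits on opposite
strands form components under reciprocal overlap ≥ 0.5 (exact coordinate
equality is too strict — engines may report the two strands offset by a
base), each component keeps its best-scoring hit, and exact ties go to the
plus strand. The filter report partitions the input exactly, so nothing
disappears unaccounted.

## Terminator model

Intrinsic terminators are detected as a stem-loop plus U(T)-tail. The
detector enumerates every arm/loop decomposition with stem length 4–20 bp,
loop 3–10 nt, at most 1 interior mismatch (the innermost and outermost
stem positions must pair), Watson–Crick pairs plus the G·U wobble. The
scoring scheme is this package's own calibrated surrogate — the original
terminator finders do not publish their internals — chosen so that
canonical terminators (≥ 6 bp clean stem, U-tail) clear the default
confidence cutoff of 70 while hairpin-free sequence never produces a call:

* pair scores G≡C +3, A=T +2, G·U +1, mismatch −3; loop penalty
  `0.5 * loop_len`;
* tail score: position-weighted T count over the 8 nt following the stem,
  weights 1.0, 0.9, … floored at 0.1 (maximum 5.2), truncated tails scored
  over the available bases;
* confidence `= 100 logistic(0.35 (hairpin + 3 tail − 18))`.

Candidates sharing a loop collapse to the highest-scoring stem (shortest
on ties); overlapping same-strand candidates then collapse to the
highest-confidence one, with exact ties all kept — that tie rule is what
makes the output invariant under strand reflection of the input, a
property the tests check exactly. Note that a strong stem alone
(hairpin > 18) can clear confidence 70 without any tail; on random
sequence the default cutoff is therefore permissive, and users wanting a
conservative track should raise `min_confidence`. The detector is
annotation-agnostic by design: whether a terminator is *relevant* is
decided downstream by the regulon logic, not suppressed at detection time.

## Regulon inference

Every annotated `promoter`/`protein_bind` feature is a potential
transcription-unit anchor. The first gene must start within
`[site_to_start_min, site_to_start_max]` (defaults 0–300 nt, mirroring the
filter) downstream of the site; the unit then extends over successive
same-strand genes and ends at (a) a same-strand terminator feature between
genes, (b) a non-coding gap ≥ `max_gap` (default 200 nt, the scale of
bacterial intergenic distances between operons) **or an intervening
opposite-strand gene**, or (c) the replicon end. The opposite-strand rule
is a deliberate design choice where the behaviour was genuinely open:
read-through across an antisense gene cannot be inferred from site and
terminator evidence alone, so extension stops with reason `gap`.

`protein_bind` sites are treated as orientation-free (a bound regulator
can activate either flank; palindromic sites are intrinsically
strandless): both directions are attempted, and when both yield units they
merge into a single divergon counted once. Promoters fire only on their
annotated strand. Per-regulator counts always sum to the number of listed
units.

The non-coding gap is measured gene-end to next-gene-start on the
top-strand coordinate line, ignoring regulatory features inside the gap.

## Genome I/O

GenBank flat files are read and written with 1-based inclusive locations
converted to 0-based half-open internally (strand `+` is the top strand
throughout the package). `join()` locations are kept as their enclosing
span with the original location string preserved verbatim and written
back, which is lossless for the bacterial case where compound locations
are rare. Feature keys follow INSDC usage: `protein_bind` (with
`bound_moiety`) for TFBS, `promoter` for sigma-factor sites, `terminator`
for terminators. Annotation operations are idempotent — duplicate features
keyed on (kind, interval, strand, bound moiety) are never added twice — so
re-running a genome scan is safe. Coverage tracks (2-column
coordinate/value or 3-column per-base depth output) are parsed and
exposed, not drawn.

## Profile optimisation

`optimize_profile()` transfers a profile to a set of related target
genomes: scan each genome at the retain score, keep hits that overlap a
seed site (orthologous sites are always retained) or that pass the context
filter and fall in the optional `target_regions` allowlist — the
operational stand-in for a curator's judgment that a downstream gene
belongs to the same physiological process; rebuild the matrix; probe
`extension_probe` (default 5) columns on each flank and keep the maximal
contiguous run with per-column IC ≥ `column_keep_ic` (default 0.3 bits —
comfortably above the sampling noise of a ~50-sequence alignment, far
below a conserved column's ~2 bits), trimming low-IC edge columns
symmetrically; repeat until the (site set, width) pair is stable or
`max_iterations` (default 5) is reached; finally calibrate with the final
site scores as training and the best rejected hits as decoys. The loop is
deterministic for a fixed configuration seed, and boundary-probe IC is
computed at pseudocount 0 so a fully conserved probed column reads exactly
2 bits.

## The synthetic genome generator

`simulate_genome()` is the package's test bed. It emulates the geometry
that the filters and the regulon logic depend on: operons laid out with
alternating strands, so that adjacent operon pairs alternately create
*converging* gaps (hosting the planted terminators and converging decoys)
and *divergent* gaps (hosting the regulatory sites of both flanking
operons); intra-operon gaps of 20–80 nt (below the 200 nt `max_gap`);
inter-operon gaps of 600–900 nt (above it, and wide enough that an
orientation-free site never reaches the facing operon within the 300 nt
window); site offsets of 20–60 nt upstream of the first gene; canonical
terminators (8 bp perfect stem, GAAA loop, 8 nt T tail) after half the
operons by default; and decoy motif copies inside genes and in converging
gaps. Planted terminators are emitted as `terminator` features — they are
part of the synthetic annotation, as in any real annotated genome — while
planted sites are deliberately *not* annotated: recovering them is the
scanner's job. Two base-pairing details are intentional: the terminator
hairpin is preceded by a CC guard that cannot pair with the T tail, so no
stem extension across the planted boundary survives the one-mismatch
limit and the detected hairpin is exactly the planted one; and the default
20-bp motif consensus is non-palindromic, so strand assignment is
informative.

Background sequence is i.i.d. at the requested GC content. That is
sufficient for everything tested here, but it understates the structured
repeats, skews and codon biases of real genomes; passing the planted-truth
checks therefore demonstrates the correctness of the algorithms, not the
false-positive rate to expect on a real chromosome, which depends on the
profile quality and the genome's composition.

Validation problem sizes were chosen to exercise every code path while
keeping the whole suite fast: 50 random profiles of width ≤ 8 for the
enumeration cross-check (65 536 words at most), ten 10-kb sequences with
four planted terminators each, one 50-kb genome with 10 operons for the
end-to-end reconstruction, and a 4-genome × 12-site ortholog set whose
planted motif is two conserved columns wider than the seed alignment for
the optimisation-recovery check.

## Known limitations

* Circular replicons are scanned without wrapping the origin.
* Compound (`join`) gene models are treated as their enclosing span.
* Terminator confidence constants are surrogates; absolute confidences are
  comparable within this package only, and the default cutoff is
  permissive on random sequence.
* The exact p-value is per-window; no genome-length E-value calibration or
  multi-hit statistics are provided.
* Overlapping genes are handled approximately by the regulon walker: the
  next gene is the next by start coordinate on the walked strand's
  direction.
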