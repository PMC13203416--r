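---
title: "Methods: comparative characterization of annotated mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative characterization of annotated mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitochar)
```

# Scope and data model

`mitochar` characterizes annotated circular vertebrate mitochondrial
genomes — the classic 37-gene architecture of 13 protein-coding genes
(PCGs), 22 tRNAs, 2 rRNAs and a control region (D-loop) — and compares
genomes against each other. It deliberately starts *downstream of
assembly and annotation*: inputs are GenBank flat files or FASTA plus a
feature table, trusted as given. No gene finding is attempted.

Conventions used everywhere:

* **Coordinates** are 1-based inclusive (GenBank convention). An
  origin-spanning feature on a circular genome is encoded with
  `end < start`; the control region is the usual case.
* **Strands** are `H` (the annotated top strand) and `L` (its
  complement). External `+/-` and `1/-1` dialects are normalized on read.
* **Alphabet** is A/C/G/T/N. Ambiguity codes other than N are rejected on
  read rather than silently coerced, because every downstream statistic
  (composition, codon usage, Hamming matching) is defined only on the
  four bases; N is carried but excluded from denominators.
* **Genetic code** is NCBI table 2 (vertebrate mitochondrial): AGA/AGG
  are stops, ATA is Met, TGA is Trp. The table is taken from Biostrings
  and validated by tests rather than re-typed.

# Composition and skew

For a region with base counts A, T, G, C (N excluded),

$$\mathrm{AT\text{-}skew} = \frac{A - T}{A + T}, \qquad
  \mathrm{GC\text{-}skew} = \frac{G - C}{G + C},$$

with the explicit convention that a zero denominator yields a skew of 0.
Per-region statistics are computed on the **H-strand slice** of each
region regardless of coding strand — the convention used in mitogenome
survey tables — with a `sense = "coding"` flag for cross-checks. Reports
round percentages to two decimals and skews to four; full precision is
kept in memory. A useful identity exploited by the tests: both skews are
antisymmetric under reverse complement.

# Gene-order metrics

Junctions are classified by walking features in start order around the
circle, including the wrap-around pair: a junction is an *overlap*
(shared bp), a *spacer* (bp strictly between), or *abutting*. Nested
features are excluded from the chain and flagged rather than merged, so
the overlap/spacer counts refer to a clean circular order. The
wrap-around junction is counted like any other; the generator can place
a spacer or an abutting junction there, so either published counting
convention can be exercised.

The codon audit reads each PCG in coding sense: start codon = first
3 nt; the stop is the final 3-mer when the length is divisible by 3,
otherwise the trailing 1-2 nt classified as an *incomplete stop* (T or
TA), the truncated codons completed to TAA by post-transcriptional
polyadenylation. AGA/AGG are complete stops under table 2.

The PCG summary reports "amino acids encoded" as `round(total PCG nt/3)`
— the arithmetic used in published summary tables (11,421 bp → 3807;
11,424 bp → 3808) — even though incomplete stops make per-gene codon
counts ragged; per-gene work always uses `floor(len/3)` complete codons.

# Codon usage and RSCU

RSCU is the observed codon count divided by its expectation under
uniform usage within its synonymous family:
$\mathrm{RSCU}_c = n_c / \bar n_{\mathrm{fam}(c)}$, i.e. (count / family
total) × family size. Families are amino-acid groups **split by codon
box** (first two nucleotides) whenever a family spans boxes: under
table 2 this reproduces the standard Leu1/Leu2 and Ser1/Ser2
bookkeeping (sizes 2 and 4) while keeping single-box families — including
the two-codon Met (ATA/ATG) and Trp (TGA/TGG) families — whole. For
amino-acid usage totals the Ser families are merged back. Stop codons
are excluded from RSCU by default (flag available, since published RSCU
figures rarely state the choice). Ties for the most-used codon break
lexicographically and are flagged, so reports are deterministic.

# Dispersed repeats

Four classes of repeat pair are detected, each a local Hamming match
between the sequence $S$ and a transform $K(S)$: Forward (identity),
Reverse (reversal), Complement (complementation), Palindrome (reverse
complement). Defaults follow common survey practice: minimum length
20 bp, at most 3 substitutions (no indels), searched on the linear
H-strand string without origin wrap — the behavior of standard tools on
deposited sequences.

A match is **maximal** if a one-bp extension on either side would exceed
the mismatch budget or run off the sequence; matches whose two copies
are sub-intervals of another match's copies (same class) are suppressed.
Where published tool semantics are underdocumented, the package's own
brute-force oracle *defines* the semantics: `oracle_find_repeats()`
scans every diagonal of the $S$ vs $K(S)$ comparison, extending from
every start column (cumulative-sum search), and is the reference
implementation for sequences up to 2 kb. The production finder seeds
candidate diagonals with shared exact k-mers, $k = \lfloor
(\ell_{\min} - m)/(m + 1) \rfloor$ by the pigeonhole principle (capped
at 15 for integer k-mer codes), so no qualifying match can be missed,
then computes maximal windows per diagonal from the sentinel formula on
mismatch positions. The two derivations are independent; the test suite
requires exact match-set equality across a seeded parameter grid.
Canonical coordinates (`start1 <= start2`, both on the input strand) and
the containment filter are shared post-processing.

With permissive parameters (length 8, 3 mismatches) random DNA is
saturated with spurious matches; both implementations stay exact but
quadratic containment filtering is bounded by a windowed candidate
expansion (a container must start within `max_length - length` bp).

# Ka/Ks (NG86)

Selection pressure per gene pair is estimated with the Nei-Gojobori
(1986) approximate method, fully specified and testable:

* **Sites.** For each codon, each of the 9 single-nucleotide changes is
  synonymous or not under table 2; changes creating stops count as
  nonsynonymous. Synonymous sites $s$ = synonymous fraction per position
  summed over positions; $s + n = 3$.
* **Differences.** Codon pairs differing at 1 position classify
  directly; at 2-3 positions the synonymous/nonsynonymous step counts
  are averaged over all orderings (2 or 6 pathways). Pathways through a
  stop codon are excluded with renormalization; if all are blocked the
  average falls back to including them (degenerate but defined).
* **Rates.** $p_s = S_d/S$, $p_n = N_d/N$ (sites averaged over the two
  sequences), each corrected with Jukes-Cantor
  $d = -\tfrac34\ln(1 - \tfrac43 p)$; $\omega = K_a/K_s$. The ratio is
  flagged undefined when $K_s = 0$ or $p \ge 3/4$.

Alignment is protein-guided: trailing partial codons and terminal stops
are stripped, proteins aligned globally (BLOSUM62, gap open 10, extend
0.5, internal stops as X), and the alignment back-mapped to codons.
Codon columns with gaps or N are dropped pairwise; fewer than 10
comparable codons is a refusal. Published Ka/Ks figures obtained with
other tools use unstated substitution models, so numeric replication is
not a goal; what the package asserts — and tests on planted data — is
*rank* behavior (which genes are fastest/slowest) and the analytic
invariants above.

# Collinearity anchors

Assembly-verification dotplots are built from maximal exact matches
(≥ 20 bp by default) between a reference and a query, in forward and
reverse-complement orientation, via shared 12-mer seeding and
per-diagonal run extension. Coverage is the fraction of reference
positions inside at least one anchor. Uniqueness filtering (dropping
anchors with overlapping spans) is optional: for a ~17 kb verification
plot plain MEMs suffice. Because circular genomes are deposited with
arbitrary numbering origins, `best_rotation()` finds the query rotation
maximizing the longest anchor via doubled-string matching.

# The synthetic generator

The generator is the package's ground-truth instrument: every analysis
statistic is validated against what was planted. It emulates the
architecture of three congeneric water-shrew mitogenomes:

* **Layout.** Canonical vertebrate gene order (WANCY cluster with the
  light-strand replication-origin spacer between tRNA-Asn and tRNA-Cys,
  the 43 bp ATP8/ATP6 overlap, ND6 plus eight tRNAs on the L strand,
  D-loop between tRNA-Pro and tRNA-Phe). Three variants fix the genome
  arithmetic at 17,218 / 17,202 / 17,211 bp with PCG totals
  11,421 / 11,421 / 11,424 bp (ND5 +3 bp in the third), nine overlaps
  totaling 78 bp, and fourteen spacers totaling 72 / 73 / 70 bp —
  values a correct pipeline must reproduce exactly. Start codons are
  ATG except ATA for ND2/ND3/ND5; stops include the incomplete T (ND4)
  and TA (COX3) and the AGA stop of CYTB.
* **Composition.** Bases are sampled i.i.d. with defaults
  A = 0.314, T = 0.336, G = 0.225, C = 0.125 — an AT-rich genome with
  negative AT-skew and positive GC-skew, matching the composition
  reported for these genomes (which list G above C). PCG interiors are
  sampled codon-wise from a non-stop codon distribution matched to the
  base probabilities, so genes are translatable without rejection
  sampling; a repair pass removes in-frame stops that arise where genes
  overlap, never touching planted start/stop codons (frame offsets in
  the layout guarantee a free base always exists).
* **Repeats.** Planted pairs get exactly the requested mismatch count
  under their class transform, plus guard mismatches just outside both
  copies so each planted match is maximal at exactly its planted
  length; the default plan puts the mode of the length distribution at
  20 bp, the dominant length in mitogenome surveys.
* **Divergence.** `evolve_pair()` plants substitutions codon by codon,
  classified at planting time. Rates are per-site proportions and the
  planted counts are deterministic (`round(rate x sites)`, placement
  random, at most one change per codon, never creating stops), so
  between-gene rank recovery is robust to the seed. Defaults chosen
  once as the study conditions: synonymous 0.10 per synonymous site;
  nonsynonymous baseline 0.0056, ATP8 at 5x (0.028) and COX1/COX2 at
  1/5 (0.0011) — yielding Ka/Ks ≈ 0.05 baseline, ≈ 0.27 for ATP8 and
  ≈ 0.01 for COX1, inside the 0.03-0.27 range typical of shrew
  mitogenome surveys, with ATP8 fastest and COX1/COX2 slowest.
  Non-coding regions mutate at a flat 3% per base; planted repeat loci
  and codons shared between overlapping PCGs are protected.

What the generator does **not** emulate: real tRNA/rRNA secondary
structure, within-genome composition heterogeneity (beyond PCG codon
structure), indels, tandem repeats in the control region, and
heteroplasmy. Passing tests therefore demonstrate algorithmic
correctness on the architecture above, not robustness to every artifact
of real assemblies.

# Pipeline and phylogenetic preparation

`run_characterization()` runs all single-genome modules per input and
the cross-genome modules (Ka/Ks table, collinearity against the first
genome, concatenated alignment, NJ tree for ≥ 3 taxa) when possible,
isolating per-genome failures. Artifacts are deterministic — no
timestamps — so identical inputs reproduce byte-identical TSV/JSON
outputs.

`concat_pcgs()` concatenates per-gene protein-guided codon alignments in
canonical order (ND1…CYTB) with a RAxML-style partition table; the
multi-sequence merge is reference-anchored (center-star): insertions
relative to the first genome open gap columns for everyone and
co-located insertions from different genomes are left-aligned rather
than mutually aligned — adequate for mitochondrial PCGs, where indels
are rare, and stated here as a known approximation. Tree inference
proper is out of scope; `nj_sanity_tree()` (K80 distances + neighbor
joining via ape, saturated distances capped at twice the largest finite
value and flagged) is a deterministic sanity check, not a substitute
for ML/Bayesian inference on the exported alignment.

# Numerical and testing choices

* All randomness flows through explicit integer seeds; generation is
  byte-reproducible.
* Oracle comparisons run on sequences up to 2 kb (the brute-force guard)
  across `min_len` ∈ {8, 12, 20} × `max_mismatch` ∈ {0, 1, 3}; the
  Ka/Ks single-difference classifier is swept over all valid codon
  pairs at Hamming distance 1.
* Test problem sizes (17 kb genomes, ≤ 2 kb oracle corpora, one evolved
  trio) were chosen so the full suite completes in a few minutes while
  every module is exercised through its public surface.
* Report rounding (2 decimals for percentages, 4 for skews/RSCU) is a
  presentation choice; comparisons in tests use exact or 1e-9
  tolerances on unrounded values.
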