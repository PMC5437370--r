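---
title: "Methods: marker discovery and multi-method DNA barcode evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker discovery and multi-method DNA barcode evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

`barcodeval` implements a two-stage workflow common in plant barcoding
studies of closely related species groups (oaks being the motivating case):
(1) comparative chloroplast-genome analysis to discover and screen candidate
plastid markers, and (2) evaluation of a panel of candidate barcodes — and
every combination of them — with four complementary species-discrimination
methods. This vignette explains the models, the tunable parameters and their
defaults, the numerical choices, and what the bundled synthetic-data
generator does and does not emulate.

## Stage 1: plastome comparison and marker screening

### Quadripartite partitioning

A plastome consists of a large and a small single-copy region (LSC, SSC)
separated by two inverted repeats (IRa, IRb). `locate_inverted_repeats()`
finds the IR pair by seeding shared k-mers (default k = 25) between the
sequence and its reverse complement and extending each seed run maximally
with zero mismatches along its anti-diagonal. The maximal-length pair at
least `min_ir_len` (default 1000 bp) long wins; among equal-length maxima
the pair with the smallest IRa start is taken, for determinism. Records
carrying two `repeat_region` annotations can be partitioned from the
annotation instead (`source = "annotated"`), validated against the
reverse-complement invariant with a 1% mismatch tolerance to absorb
annotation and boundary ambiguity. All coordinates are 0-based half-open;
GenBank's 1-based closed intervals are converted on read, so a single
convention holds everywhere internally.

### Single-copy comparison

`compare_single_copy_regions()` aligns LSC with LSC and SSC with SSC after
removing the IRs. A full dynamic program over ~90 kb regions is unnecessary
for two closely related plastomes, so homology is established by an anchor
chain: unique shared 20-mers are collapsed into collinear blocks and the
longest consistent chain selected; the short segments between anchors are
aligned with a banded global alignment (band width `2|len_a - len_b| + 16`).
The segment aligner uses affine gap costs (mismatch 1, gap open 3, gap
extend 0.5). The open cost matters: with linear gap costs an optimal
alignment may split one contiguous deletion into two runs to buy back a
single mismatch, which fragments indel events; the affine penalty makes one
run per event strictly optimal, so planted edit scripts are recovered
exactly in the package's tests. SNPs are mismatch columns; each maximal run
of gap columns is one gap event. `anchored_fraction` is the proportion of
the reference region inside anchor blocks; below 0.5 the comparison aborts
as unreliable rather than reporting counts from a dubious chain.

### Repeats, primers, diversity screens

`find_repeats()` reports all maximal exact repeated pairs (forward and
palindromic) with unit lengths 8–50 bp by default, excluding mononucleotide
units and, optionally, anything overlapping the IRs (which would otherwise
saturate the output). Palindromic hits are required to occupy two disjoint
locations; a maximal extension that folds onto itself is a self-palindrome,
not a repeat pair. The implementation is checked against a naive all-pairs
maximal-extension scan on randomized sequences.

`pick_primer_windows()` scans a pairwise-aligned region for primer-sized
windows identical in both genomes (18–24 nt, Tm 50–65 °C; Wallace rule
`2(A+T) + 4(G+C)` up to 20 nt, the GC formula `64.9 + 41(GC − 16.4)/len`
above) and pairs windows bracketing at least one variant column at a product
length of 400–1100 alignment columns. Tiling is greedy left-to-right with
non-overlapping products preferred: reproducibility is favored over
primer-quality optimality, and self-complementarity checks are deliberately
out of scope. The window-scan granularity is this package's own choice; no
published parameterization exists for splitting a variable region into
"suitable fragments".

Marker screening combines two filters (`screen_markers()`): mean per-species
nucleotide diversity π > 5 × 10⁻⁴ and amplification success ≥ 80%.
Amplification success is observed wet-lab data and always an input, never
computed. π is the mean pairwise p-distance among conspecifics, averaged
unweighted over species with at least two individuals (a pooled mode over
all conspecific pairs is available; the averaging convention is not uniquely
pinned down in common practice). For markers containing indels the
deletion–insertion polymorphism statistic (`dip_statistic()`) treats each
maximal gap region as a multiallelic locus whose alleles are the distinct
gap patterns, with unbiased diversity `h = n/(n−1)(1 − Σp²)` — the
convention under which 9 individuals with a 6/3 allele split give exactly
h = 0.5.

## Stage 2: four-method barcode evaluation

All methods start from aligned per-marker matrices bound to a species map.
Cleaning (`clean_alignment()`) drops columns whose `N`/`?` fraction exceeds
0 (any ambiguity, by default) and poly-A/T blocks of ≥ 8 columns present in
≥ 50% of rows; the poly-A/T thresholds are package choices, with provenance
of kept columns recorded. Indels are recoded by simple indel coding
(`code_indels()`): each distinct maximal gap span becomes one binary
character (`T` present / `A` absent, `?` when a row's gap strictly contains
the span). The coded columns are appended and participate in distances and
character methods — indels are treated "as substitutions" — and this is
toggleable (`indel_coding = FALSE`).

**Distance method.** Pairwise p-distances use pairwise deletion: only
columns where both sequences carry an unambiguous base are compared; empty
overlap yields `NA` rather than a fabricated distance.
`barcode_gap_assess()` ranks all distances and declares a barcode gap when
the consecutive jump straddling the maximum intraspecific divergence exceeds
`gap_factor` (default 2) times the jump's lower edge — a scale-free
quantification of "sudden increase": a genuine gap dwarfs the distances
below it, while ordinary spacing in the sparse upper tail of the
interspecific distribution does not. When the lower edge is zero the median
positive step is the fallback scale. `abgd_partition()` is a simplified,
deterministic re-implementation of automatic barcode gap discovery: the
threshold is the lower edge of the widest ranked-distance gap whose upper
edge exceeds the prior; groups are single-linkage components; recursion
re-examines each group over 100 geometrically spaced priors in [P/10, P]
until stable. A recursive split is accepted only when the within-group gap
passes the same scale-free suddenness test; unguarded widest-gap recursion
would shatter genuine conspecific clusters, whose near-continuous distance
spread always contains *some* widest gap. The original tool's slope-based
detection and Monte-Carlo machinery are intentionally not replicated. A
species is delimited when its individuals form exactly one group with
nobody else; all species, including singletons, count in the denominator.
Maximum intraspecific divergence carries a bootstrap standard error from
column resampling (default 1000 replicates). Welch's t and the Wilcoxon
rank-sum test (normal approximation, tie-corrected; the statistic is
reported as the rank-sum W) compare intra- against interspecific distances,
pooled or per species.

**Similarity method.** `top_hit_classify()` replaces a local alignment
search with identity over pairwise-shared unambiguous columns (sequences are
already aligned, and seeded heuristics add nondeterminism without benefit at
this scale). The query itself is excluded; a species is identified when
every individual's best hit is conspecific, with any heterospecific tie at
the top counting as failure (the strictest reading; how ties were originally
scored is not documented). Singletons are ineligible — with self-exclusion
they cannot succeed.

**Character method.** `induce_formulas()` builds per-species DNF formulas
over (column, state) literals. Species with pure single-position diagnostics
(`find_diagnostic_characters()`) get one single-literal disjunct per
diagnostic. Otherwise an exact vectorized search tries every perfect
two-literal conjunction (literals satisfied by all positives, paired so no
negative satisfies both — a crossproduct over negative-coverage indicators);
only if that fails does greedy growth take over, choosing literals that
minimize `50 × positives_excluded + 800 × negatives_covered`, preferring
literals that lose no targeted positive. The weight asymmetry mirrors the
original tool's published cost settings: false positives are expensive,
false negatives cheap. Ambiguity codes never satisfy a literal, and an
ambiguity code in a non-target individual whose expansion includes a
candidate state blocks that diagnostic (conservative rule) — heterozygotes
cannot inflate diagnosability. Classification assigns an individual to the
unique species whose formula it satisfies; zero or multiple matches leave it
unassigned. Training and testing use the same matrix, matching the original
self-verification protocol; the strict all-individuals-correct rule scores a
species as identified.

**Tree method.** `nj_tree()` is canonical neighbor joining
(`Q = (n−2)d(i,j) − R_i − R_j`, ties broken on the lexicographically
smallest label pair, negative branch lengths clamped to zero with the
deficit moved to the sister branch so path lengths are preserved). It is
consistent: on additive matrices it returns the generating topology and
branch lengths exactly, which the tests verify on random trees, with an
established independent implementation as cross-check. Bootstrap supports
resample columns with replacement; replicate r is seeded `seed + r`, so
supports are bit-reproducible. Monophyly is judged on the original-data
tree (not a consensus): a species is identified when one edge's removal
separates exactly its leaves; species with one individual are excluded from
the denominator and reported separately.

**Combination grid.** `evaluate_all()` enumerates all non-empty marker
subsets (size, then lexicographic order), concatenates each into a
supermatrix — individuals missing a marker are `?`-filled, which pairwise
deletion absorbs, matching the unequal amplicon counts of real panels — and
runs the requested methods with one shared distance matrix per combination.
Method failures on a combination are recorded in a `status` column and the
run continues. Eligibility denominators default to: distance, all species;
similarity/character/tree, species with ≥ 2 individuals.

## The synthetic-data generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, so the whole pipeline is testable without any sequence download.
Per marker: an ancestral i.i.d. sequence; species consensus = ancestor
mutated per site with probability `d_inter` (uniform over the three
alternatives, a Jukes–Cantor-like kernel with no transition bias — p-distance
methods are insensitive to it); individuals = consensus mutated at
`d_intra`. Species sit on a star phylogeny (the simplest structure that
exercises every method). One reserved column per species per marker can be
forced to a species-unique state (`p_diag`); reserved columns are masked
from *all* stochastic edits — substitutions, heterozygote coding, deletion
spans — because a single IUPAC code containing a diagnostic state in the
wrong individual would, under the conservative ambiguity rule, silently
destroy the planted truth. Species-specific deletions (3–10 bp, probability
`indel_rate`) land at distinct coordinates. For plastid markers an
individual's whole haplotype (all plastid markers jointly, as one linked
molecule) is redrawn from another species' consensus with probability
`p_share`, emulating chloroplast capture and incomplete lineage sorting; a
swapped individual carries the donor's plastid diagnostics and gaps, while
its nuclear markers are untouched. Nuclear markers receive two-base IUPAC
codes at rate `p_het`.

`expected_pairwise_distance()` gives the closed-form expectation: each
mutation step has identity eigenvalue `1 − 4d/3`, and for two lineages with
total eigenvalues `λ₁ λ₂` the expected p-distance is `¾(1 − λ₁λ₂)` (so an
intraspecific pair at `d_intra = 0.01` expects `2d − 4d²/3 ≈ 0.0199`). The
generator is validated against this expectation at L = 10 000 within three
binomial standard errors.

Two presets define the study conditions used throughout the tests and the
acceptance script: **clean** (10 species × 5 individuals; two plastid and
one nuclear marker, 600 bp each; `d_intra = 0.003`, `d_inter = 0.05`;
planted diagnostics; `indel_rate = 0.2`; `p_het = 0.02`; no sharing), under
which all four methods discriminate all species, a barcode gap exists, and
the partitioner delimits 10/10; and **hybrid** (clean plus `p_share = 0.3`),
under which distance- and tree-based rates collapse while the
character-based method survives on nuclear diagnostics — reproducing the
qualitative ordering reported for real oaks, where the character-based
method performed best and the distance-based method worst. What passing
these tests does *not* show: real barcode data have rate heterogeneity
across sites, nested clade structure, alignment error, pseudogenes and
missing data patterns correlated with taxonomy; the generator makes no
attempt at coalescent realism or oak demography. Synthetic results
demonstrate the machinery is correct, not that any particular rate will be
achieved on real sequences.

## Reference-scale synthetic plastome

`synthetic_plastome()` builds a random LSC + IR + SSC + revcomp(IR) genome
at user-set dimensions and GC content, defaulting to the published region
lengths of a Fagaceae plastome (LSC 91,121, SSC 20,150, IR 25,051,
GC 36.79%). It is synthetic: it validates the locator, summaries and
comparison machinery at realistic scale and is not a substitute for the real
accession's gene content. One constructed detail: the SSC's terminal base is
re-drawn if it complements the SSC's first base, because otherwise the true
maximal IR pair extends one step into the SSC and the recovered boundaries
would differ from the construction by design rather than by error. (The
published region lengths for this genome sum to 161,373, not the printed
161,304 total; the companion genome's printed values are internally
consistent at 160,799. The package keeps the arithmetic invariant
`total = LSC + SSC + 2·IR`.)

## Numerical choices and degenerate inputs

- Distances with zero shared sites are `NA`; NJ refuses `NA` matrices with
  an instruction to impute or drop, rather than guessing.
- The ABGD prior must be positive; when a dataset has zero observed
  intraspecific divergence the evaluation engine substitutes half the
  smallest positive distance.
- Degenerate zero-variance samples in the t test (all-identical distances)
  are reported as infinite separation (p = 0) or none (p = 1) instead of
  erroring.
- Problem sizes in the tests — 10 × 5 individuals, 600 bp markers, 200–1000
  bootstrap replicates, 10 kb comparison regions, 100-case oracle sweeps —
  were chosen so the full suite settles in a few minutes while keeping every
  statistical check well-powered.

## Known limitations

- The ABGD re-implementation is a deterministic approximation; it is a
  partition oracle for a stated prior, not a replacement for the original
  tool's recursive slope analysis.
- Greedy formula induction beyond two literals is heuristic; optimality is
  guaranteed only for one- and two-literal conjunctions.
- The similarity method assumes pre-aligned, coordinate-compatible inputs;
  it does not reproduce E-values or word-seeded local search.
- Printed reference rates from the motivating oak study (30.30% single-marker
  bests, 84.85% for the best six-marker character-method combination,
  17.14% distance-based, t = 3.811 / W = 32563.5) depend on ~1,400 curated
  GenBank sequences and are reference values only; nothing at desk scale can
  or should reproduce them, and the package does not claim to.
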