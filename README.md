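# barcodeval

Chloroplast marker discovery and multi-method DNA barcode evaluation for
closely related plant species groups.

## The problem

Species-rich, recently diverged plant lineages — oaks are the canonical
example — resist DNA barcoding: plastid markers evolve slowly, interspecific
hybridization and incomplete lineage sorting let chloroplast haplotypes
cross species boundaries, and the distributions of intra- and interspecific
genetic distances overlap, erasing the "barcode gap" that distance-based
identification relies on. Studies of such groups therefore (1) mine whole
plastome comparisons for candidate markers and (2) evaluate candidate
barcodes with several discrimination methods at once, because the methods
disagree systematically.

`barcodeval` implements both stages as tested, reusable R functions:

**Marker discovery.** Quadripartite plastome partitioning (LSC / IRa / SSC /
IRb) by maximal inverted-repeat detection; anchor-chained comparison of
single-copy regions with affine-gap banded alignment (SNP and gap-event
counts); maximal exact repeat scanning (8–50 bp, mononucleotide runs
excluded); conserved-flank primer window selection (18–24 nt, Tm 50–65 °C,
products 400–1100 bp); per-species nucleotide diversity
(π, mean pairwise p-distance) and the multiallelic deletion–insertion
polymorphism statistic `h = n/(n−1)(1 − Σp²)`; marker screening by
π > 5·10⁻⁴ and amplification success ≥ 80%.

**Barcode evaluation.** Four species-discrimination methods over every
combination of candidate markers:

| method | engine | species identified when |
|---|---|---|
| distance | ABGD-style partitioning at the max-intraspecific prior | its individuals form one group alone |
| similarity | leave-self-out top-hit classification | every individual's top hit is conspecific |
| character | diagnostic (column, state) logic formulas in DNF | all individuals are uniquely assigned to it |
| tree | neighbor joining (p-distance, pairwise deletion) + bootstrap | its leaves form a monophyletic clade |

Supporting machinery: alignment cleaning with provenance, simple indel
coding (gap spans as binary characters, `?` for strictly containing gaps),
barcode-gap assessment over ranked distances, Welch-t / Wilcoxon
intra-vs-inter tests, and a seeded synthetic dataset generator with planted
diagnostics, species-specific indels, IUPAC heterozygotes and plastid
haplotype sharing so the entire pipeline is testable offline.

## Worked example

Simulate a study-shaped dataset in the regime where plastid haplotypes cross
species boundaries (the `"hybrid"` preset: 10 species × 5 individuals, two
plastid and one nuclear 600-bp marker, 30% plastid haplotype sharing), then
evaluate all 7 marker combinations with all four methods:

```r
library(barcodeval)

sim <- simulate_dataset(preset_config("hybrid", seed = 42))
rep <- evaluate_all(sim$alignments, sim$map)
glance(rep)
#> # A tibble: 4 × 4
#>   method     n_combinations best_rate best_combination
#>   <chr>               <int>     <dbl> <chr>
#> 1 character               7       100 nucA
#> 2 distance                7        90 nucA
#> 3 similarity              7       100 nucA
#> 4 tree                    7       100 nucA
```

Every method's best combination is the nuclear marker: the shared plastid
haplotypes poison plastid-only combinations (their rates in `rep` fall to
0–20%), while the character method stays at 100% on any combination that
includes `nucA`, because planted nuclear diagnostics survive hybridization.
`rate` is the percentage of eligible species identified;
`identified_species` lists them per row.

The pooled plastid markers show why distance-based barcoding fails here —
the maximum intraspecific divergence (0.12, inflated by hybrids) sits inside
the interspecific distribution, so no sudden increase exists:

```r
dm  <- p_distance_matrix(concatenate_markers(sim$alignments[c("cpA", "cpB")]))
glance(barcode_gap_assess(dm, sim$map))
#> # A tibble: 1 × 6
#>   n_distances d_intra_max gap_found gap_lo gap_hi gap_factor
#>         <int>       <dbl> <lgl>      <dbl>  <dbl>      <dbl>
#> 1        1225        0.12 FALSE         NA     NA          2
```

`autoplot(barcode_gap_assess(...))` draws the ranked-distance curve with the
max-intraspecific line; `autoplot(rep)` draws rate-vs-combination-size boxes
per method. `write_report(rep, "report.tsv")` and `write_newick()` export
results; `read_genbank()`, `read_fasta_alignment()` and `read_species_map()`
ingest the standard input formats.

The genome side works the same way from a `genome_record` (a random
construction carries no long repeats, hence `n_repeats = 0` here; at the
8-bp default minimum, chance repeats dominate any genome this size):

```r
g  <- synthetic_plastome(seed = 1)        # Fagaceae-dimensioned test genome
qm <- locate_inverted_repeats(g)
genome_summary(g, qm, find_repeats(g, min_len = 20, exclude = qm))
#>                   id total_bp lsc_bp ssc_bp ir_bp gc_percent n_repeats
#> 1 synthetic_plastome   161373  91121  20150 25051      36.69         0
```

## Vignette

`vignettes/barcode-evaluation-methods.Rmd` documents the models and
assumptions behind each method, the default parameters and where they come
from, the synthetic generator's design and its limits, and the numerical
decisions (tie-breaking, clamping, degenerate inputs).
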