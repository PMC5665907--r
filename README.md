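# editaccess

Population-scale analysis of A-to-I RNA editing and its structural
consequences for miRNA-mediated mRNA degradation.

## The scientific problem

ADAR enzymes deaminate adenosines to inosines — read as guanosines — mostly
in 3' UTRs. An A→G change inside a double-stranded region stabilises it: an
A·C mismatch becomes a G-C pair, an A-U pair a G·U wobble. Tighter local
structure lowers the accessibility (the probability that a 7-nt window is
entirely single-stranded) of nearby miRNA seed-match sites, shielding the
edited transcript from AGO2-miRNA degradation. Two population-level
signatures follow:

* transcript abundance rises with editing at sites near miRNA targets, and
* because degradation removes mainly *unedited* copies, the observed editing
  level in the surviving RNA pool is inflated and inter-individual
  differences are buffered.

For a site with true editing level *e* and survival probabilities *s_u*
(unedited) and *s_e* (edited):

```
observed = e·s_e / (e·s_e + (1−e)·s_u)        abundance = e·s_e + (1−e)·s_u
survival = exp(−k · AGO2 · accessibility)
```

`editaccess` is for computational biologists who want to run this analysis
chain on mismatch pileup tables and expression matrices — or to study its
statistical behaviour on fully synthetic populations with a known ground
truth. It provides:

* **sitecall** — an LLR filter cascade for calling A-to-I sites from pileup
  tables (LLR ≥ 2, depth ≥ 10, ≥ 2 edited reads, level ≥ 0.1, SNP / simple
  repeat / homopolymer / splice-junction exclusions), genomic-context
  classification and population-level site selection;
* **popstats** — prevalence, per-individual mean editing and editing index,
  hypergeometric sharing, exact rank-sum differential editing with the
  0.067 effect-size floor, variance in editing explained by ADAR
  expression, UAG-context enrichment, RPKM;
* **structacc** — 7-mer accessibility via ViennaRNA (`RNAplfold -u 7 -L 300
  -W 400`, 1001-nt windows), edited-vs-unedited relative accessibility
  profiles, opposite-nucleotide calls in MFE structures, control
  adenosines, accessibility–expression correlation;
* **mirtarget** — canonical seed matching (7mer-A1 / 7mer-m8 / 8mer),
  editing-to-target distances, tertile stratification with covariate
  matching, knockdown-vs-control contrasts;
* **syndata** — generators for hairpin 3' UTRs with an editable A opposite
  C or U, population expression profiles, the degradation model, and
  pileup-level read sampling ([`simulate_cohort()`] ties them together).

## Worked example

```r
library(editaccess)

# the degradation model: a site edited at 0.2 whose unedited copies survive
# at 0.5 appears edited at 1/3 in the surviving pool
apply_degradation(e = 0.2, s_u = 0.5, s_e = 1.0)
#> $observed
#> [1] 0.3333333
#> $abundance
#> [1] 0.6

# a designed hairpin 3' UTR: the editing-site A sits in an A·C mismatch,
# the A->G edit completes the helix and closes nearby 7-mers
tx <- generate_hairpin_utr(length = 120, stem_len = 12, edit_opposite = "C",
                           target_distance = 4, seed = 3)
fw <- fold_window(tx$sequence, tx$edit_pos)
ra <- relative_accessibility(fw$unedited, fw$edited, fw$site_in_window,
                             max_offset = 10)
mean(ra$log2_ratio, na.rm = TRUE)
#> [1] -6.52
```

The unedited MFE structure (−25.0 kcal/mol) leaves the site A unpaired; the
edited one (−31.6 kcal/mol) pairs it, and the mean log2 change in 7-mer
accessibility within ±10 nt of the site is −6.5 — editing locks the region.

The full synthetic pipeline (simulation → site calling → population
statistics → structure → miRNA targeting) runs in seconds:

```r
dir <- tempfile()
run_pipeline(default_run_config(seed = 7), dir)
summary_report(dir)
#> editing pipeline run d2eeb56e6084ec2493a2bb92b1fdc8ef (seed 7)
#> ----------------------------------------------------------------
#> syndata    60 individuals x 24 genes simulated
#> sitecall   699/1143 candidate sites retained; A-to-G fraction 0.864
#> popstats   19 population sites selected; 0 differential between populations
#> structacc  mean log2 accessibility change (+/-10 nt) -4.729; 68.4% of sites negative
#> mirtarget  AGO2 vs mean editing r = 0.07; accessibility-expression r = -0.977
```

Read: of 1143 site × individual pileup records, 699 pass the filter cascade;
86.4% of distinct candidate sites are A-to-G; editing lowers accessibility
around most sites; AGO2 expression correlates positively with observed
editing while target-site accessibility change correlates negatively with
the expression shift of edited individuals — the two signatures of
preferential degradation of unedited transcripts.

The methods vignette (`vignettes/editing-structure-degradation.Rmd`)
documents the model, the generator's design and defaults, and the numerical
conventions.

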