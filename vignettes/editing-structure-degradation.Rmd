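---
title: "Methods: A-to-I editing, local RNA structure, and miRNA-mediated degradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A-to-I editing, local RNA structure, and miRNA-mediated degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editaccess)
```

## The problem

Adenosine-to-inosine (A-to-I) editing by ADAR enzymes is abundant in 3'
untranslated regions, where inosine is read as guanosine. Because an A-to-G
change inside a double-stranded region usually stabilises the helix (an A·C
mismatch becomes a G-C pair; an A-U pair becomes a still-paired G·U wobble),
editing can tighten local RNA structure, lower the single-strandedness of a
nearby miRNA seed-match site, and thereby shield the edited transcript from
AGO2-miRNA-mediated degradation. Two consequences follow at the population
scale:

1. transcript abundance becomes editing-dependent (edited copies survive), and
2. the *observed* editing level in the surviving RNA pool exceeds the level
   at which the pool was edited, compressing level differences between
   individuals ("buffering").

`editaccess` implements the analysis chain for this mechanism — site calling
from mismatch pileups, population editome statistics, structure accessibility,
miRNA target-distance analyses — together with a generative model of the
mechanism itself, so every stage can be validated end to end against a known
ground truth.

## The degradation model

For one site with true editing level $e$, let $s_u$ and $s_e$ be the survival
probabilities of unedited and edited molecules. The surviving pool has

$$\mathrm{abundance} = e\,s_e + (1-e)\,s_u, \qquad
  \mathrm{observed} = \frac{e\,s_e}{e\,s_e + (1-e)\,s_u}.$$

When $s_e \ge s_u$, observed $\ge e$, and for two sites with true levels
$e_1 < e_2$ sharing $s_u < s_e$ the observed ratio is strictly smaller than
$e_2/e_1$ — the buffering claim, provable directly from the closed form and
asserted over a parameter grid in the test suite:

```{r degradation}
apply_degradation(e = 0.2, s_u = 0.5, s_e = 1.0)
```

Survival is linked to structure by
$s = \exp(-k \cdot \mathrm{AGO2} \cdot \mathrm{accessibility})$, the simplest
monotone map from nonnegative degradation pressure into $(0, 1]$. The paper
trail behind this package establishes the direction of the effect, not a
functional form; the exponential link is this package's choice.

## Structure accessibility

Folding is delegated to the ViennaRNA command-line engine: minimum free
energy structures from `RNAfold`, and the partition-function probability
that a 7-nt window is entirely unpaired from `RNAplfold` with `-u 7 -L 300
-W 400`. For an editing site, a 1001-nt window centred on the site is folded
twice — once as-is, once with the A replaced by G (the standard proxy for
inosine) — and the per-offset log2 ratio of edited over unedited 7-mer
accessibility is the *relative accessibility* profile. The 7-mer is centred
on the reported offset; offsets where a centred 7-mer does not fit are
reported missing rather than zero. Identity substitution gives an exactly
zero profile, which the tests assert.

The *opposite nucleotide* of a site in an MFE structure is the partner base
when the site is paired; when unpaired, the neighbour rule applies: if the
5' neighbour pairs with $j$, the base at $j-1$ is taken (antiparallel
geometry), else if the 3' neighbour pairs with $j$, the base at $j+1$;
otherwise the call is ambiguous ('N'). When both neighbour branches would
apply, the 5' branch wins — the tie is not specified anywhere authoritative,
so it is fixed for determinism and documented here.

## The synthetic study

The generators emulate, at desk scale, the statistical structure the
analyses assume:

* **Individuals** (`generate_population()`): per-population log-normal
  expression of ADAR1/2/3, AGO2 and a miRNA. Defaults: ADAR1
  $\mathrm{lognormal}(0, 0.4)$, AGO2 $(0, 0.5)$, with population-specific
  ADAR1 location shifts available to emulate between-population expression
  differences.
* **True editing**: per site, $e = 0.8\,\sigma(2(\log \mathrm{ADAR1} - m))$
  with site midpoints $m \sim U(0,1)$ — editing responds to ADAR1 dosage
  without a stated functional form in the source material; a logistic link
  in log expression is the package's choice. A per-site prevalence
  ($U(0.4, 0.9)$) gates which individuals edit at all, so every site retains
  truly unedited individuals — as in real populations, where site prevalence
  spans rare to near-universal. Without this, the edited-versus-unedited
  expression contrast would be undefined exactly at the strongest sites.
* **Hairpin 3' UTRs** (`generate_hairpin_utr()`): a stem whose 5' arm
  carries the editable A (opposite C or U in the 3' arm), a GNRA-type loop,
  and pyrimidine-only flanks that cannot base-pair with themselves. The
  stem's outer arm clasps the last 2-4 nt of a 7mer-m8 seed site, with an
  AU-rich segment between seed and editing site and a short G/C anchor
  inside. This geometry matters: prototyping showed that a seed site placed
  in fully unstructured flank shows *no* accessibility response to the edit
  at any distance, because the partition function barely couples an interior
  helix change to free single-stranded regions. With the clasped design the
  edit changes target accessibility by $-7..0$ log2 units, decaying with the
  editing-site-to-target distance over roughly 2-18 nt. Distances in the
  cohort are therefore drawn from 2-18 nt (weighted toward 2-6) — a
  compressed analogue of the hundreds-of-nt distances in real 3' UTRs,
  within which single-substitution structural effects actually propagate.
* **Degradation**: the survival link receives the accessibility *relative to
  the more accessible allele* of each gene (max-normalised). Raw unpaired
  probabilities at partially clasped seeds are of order $10^{-3}$, which
  would push all survivals to 1 and erase the mechanism at the default
  $k = 1$; normalising preserves the fold-derived log2 ratio as the only
  structural signal while giving survival a usable dynamic range.
* **Reads** (`simulate_pileup()`): edited-read counts are binomial in the
  observed level at negative-binomial depths (mean 50, size 5); sequencing
  errors are injected per read and distributed uniformly over the other
  substitution types; Phred qualities follow a clipped normal(35, 5) —
  a typical short-read quality profile.
* **Gene classes**: 80% of genes carry an editing site; of those, 20% have
  their seed site scrubbed (edited but untargeted — the control group for
  knockdown contrasts), and the remaining 20% of genes are unedited targets
  (the control group for expression-shift contrasts).

What the generator does *not* emulate: alignment artefacts, hyper-edited
read clusters, Alu-repeat mappability structure, covariation between ADAR
and AGO2 expression, and UTRs with several editing sites or several miRNAs.
Passing end-to-end tests therefore demonstrate internal consistency of the
method chain under the stated model, not performance on real libraries.

## Site calling

Candidate mismatch sites pass a fixed cascade: log-likelihood ratio
$\ge 2$ against an errors-only model, depth $\ge 10$, edited reads $\ge 2$,
level $\ge 0.1$, not at a known SNP, not in a simple repeat, not inside a
homopolymer run longer than 4 nt, and not intronic within 4 nt of a splice
junction. All thresholds are closed on the passing side. The LLR maximises a
variant-fraction likelihood over alt-supporting reads with per-read error
probabilities $10^{-Q/10}$; the exact formula of the original caller is not
public, so this package's form is documented here, with an optional
half-weight for read-end mismatches (off by default) and a configurable
logarithm base (base 10 default). The surviving set is provably independent
of rule order; only the "first failing rule" label depends on the fixed
evaluation order (llr, coverage, edited reads, level, SNP, repeat,
homopolymer, splice).

Population-level selection keeps sites edited (alt $\ge 2$, level $\ge 0.1$)
in $\ge 3$ individuals and testable (depth $\ge 10$) in $\ge 10\%$ of the
population. "Testable" (depth $\ge 10$) also defines the denominator of
site prevalence (rare $\le 10\%$, prevalent $> 90\%$) and the missingness
of the editing matrix.

## Statistics

* Wilcoxon rank-sum: own implementation — exact enumeration of midrank-sum
  permutations when both groups have $\le 8$ observations (ties get
  midranks), otherwise a normal approximation with tie-corrected variance
  and continuity correction. Exactness under ties at small $n$ is required
  by the differential-editing test and verified against full enumeration.
* Differential editing: two-sided rank-sum $p < 0.01$ *and* an absolute
  mean-level difference above $1/15 \approx 0.067$ — one edited read at
  read coverage 15. No multiple-testing correction by default (a
  Benjamini-Hochberg option exists on the p-values if desired), matching
  the raw-p convention of the source analysis.
* Set sharing: upper-tail hypergeometric probability against the full
  background of analysed sites.
* Variance in editing explained by ADAR expression: per-site least-squares
  fit of level on ADAR1/2/3 with intercept, eligible when testable in more
  than 10 individuals with at least two distinct levels. Note that with a
  saturating (logistic) true dose-response, the population $R^2$ of the
  *linear* model is the estimand — it is systematically below the
  deterministic variance fraction, by about 0.1 for sites saturating at the
  population's expression extremes. The recovery test therefore compares
  the $n = 500$ estimate against a moment-based evaluation of that linear
  estimand at large $n$, not against the noise-free variance share.
* Tertile stratification: rank-based tertiles with first-occurrence tie
  breaking; high-versus-low comparisons require every matched covariate to
  be indistinguishable between the groups (rank-sum $p > 0.1$) and at
  least 3 individuals per group, otherwise the comparison is reported
  infeasible rather than silently skipped.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally (BED convention); VCF-like
  export is 1-based.
* Depth-0 pileups are flagged untestable, never treated as level 0.
* Accessibility windows truncate symmetrically at sequence ends; window
  bounds are recorded on the fold result.
* Editing-to-target distance is edge-to-edge (0 when the site lies inside
  the seed interval); nearest-target ties break toward the 5' site.
* Sliding distance windows (10 nt, step 1) with no genes are dropped;
  correlations over fewer than 3 windows, or with zero variance, are
  reported as undefined with an explicit status.
* All generators take integer seeds and are bit-for-bit reproducible;
  derived seeds stay below $2^{31}$.

## Problem sizes

The packaged end-to-end study uses cohorts of 200 individuals by 50 genes
across 20 seeds at $k = 1$; the demonstration pipeline scenario uses 60
individuals by 24 genes; structural fixture sets use 20 hairpins (14 with C
and 6 with U opposite the site, mirroring the C-over-U excess at real
editing sites). These sizes give stable directions for all reported
statistics while keeping a full run in minutes on one CPU.

## Known limitations

* The degradation link and the logistic editing response are simple
  single-parameter forms; real dose-response curves and RISC kinetics are
  richer.
* Accessibility is computed for the annotated target site of the designed
  miRNA only; competition between miRNAs and RBP occupancy are out of scope.
* The seed matcher covers canonical 7mer-A1 / 7mer-m8 / 8mer sites; no
  supplementary 3' pairing or conservation scoring — externally predicted
  target sites can be supplied as BED input instead.
* The site caller starts from pileup-style mismatch tables; read alignment
  and mutual-information-based SNP discrimination are upstream concerns and
  not reimplemented here.
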