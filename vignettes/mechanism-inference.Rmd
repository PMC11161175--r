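---
title: "Inferring the mechanism of facultative parthenogenesis from heterozygosity patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the mechanism of facultative parthenogenesis from heterozygosity patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(automixia)
```

## The problem

Facultative parthenogenesis (FP) — the occasional development of an
unfertilized egg in an otherwise sexually reproducing species — requires
some route back to diploidy from a haploid or half-way meiotic product.
The candidate routes leave different genomic fingerprints in the
offspring:

* **Central automixis** (fusion involving a first-polar-body product):
  the fused nuclei carry chromatids of *opposite* centromere origin, so
  heterozygosity is retained near centromeres and eroded only distal to
  crossovers.
* **Terminal automixis** (fusion of the egg nucleus with the second
  polar body, its sister chromatid): the fused chromatids share a
  centromere origin, so the offspring is homozygous near centromeres and
  heterozygous only distal to crossovers.
* **Post-meiotic gamete duplication**: the haploid oocyte genome is
  replicated without cell division — the offspring is homozygous at
  *every* position.
* **Sexual reproduction** (the control): maternal heterozygosity is
  complemented by a paternal allele at essentially every informative
  site.

This package simulates all four routes over an explicit meiosis model,
re-implements a deliberately strict allele-balance heterozygosity caller
for read pileups, and turns the qualitative fingerprints above into a
quantitative classifier. Around that core it provides the three
supporting analyses used in FP studies: microsatellite
parentage exclusion, a population-level heterozygosity outlier screen
(generalized ESD / Rosner test), and mixoploidy quantification from
erythrocyte counts and DNA-content histograms.

## The meiosis model

Each chromosome is a bivalent of four chromatids; chromatids 1–2 are the
sisters of homolog A, 3–4 of homolog B, and sisterhood (centromere
origin) is immutable. Crossover counts are Poisson per chromosome arm
(`crossover_rate`, default 2), positions uniform within the arm; each
crossover picks one chromatid of each homolog uniformly at random (no
chromatid interference) and exchanges the segments on the telomere side
of the crossover point. `obligate_crossover` adds the obligate chiasma:
a chromosome that drew zero crossovers receives one at a length-weighted
uniform position. MI and MII segregation are independent fair choices
per chromosome; the roles `egg`, `pb2_sister`, `pb1_x`, `pb1_y` then
define every reproduction mode as a deterministic pairing
(`?make_offspring`).

Two consequences of this model are worth spelling out, because they
shape the classifier:

* For a site separated from the centromere by exactly one crossover,
  central automixis retains heterozygosity with probability 1/2, while
  terminal automixis retains it with probability **1** (exactly one
  sister chromatid of the egg pair is recombinant, so egg and second
  polar body always differ distal to the crossover). Both values are
  reproduced exactly by `retention_oracle()`, which enumerates all
  chromatid-involvement and segregation configurations with equal
  weights, and the Monte-Carlo simulator is tested against it.
* With many crossovers between centromere and site, the retention of
  *both* automixis modes converges to the same parity limit of 2/3 (the
  four origins `{A,A,B,B}` become exchangeable across chromatids). The
  distal genome therefore does **not** discriminate central from
  terminal automixis at realistic crossover numbers — only the
  pericentromeric genome does, where central retention tends to 1 and
  terminal retention to 0 deterministically.

## The heterozygosity caller

The caller reproduces a deliberately conservative counting rule rather
than a genotype-likelihood model: a site is heterozygous iff its
coverage is even, exactly two bases have reads, and the two counts are
equal; odd-coverage sites are discarded. In `mean_coverage` mode the
scan is further restricted to sites whose coverage equals the mean
coverage rounded up to the next even integer (`target_coverage()`;
18.31 becomes 20) — in real WGS data, sites above average coverage are
enriched for collapsed repeats whose paralogous differences masquerade
as heterozygosity, so excluding them trades sensitivity for specificity.

The price of the equal-split rule is a known, calculable sensitivity:
at coverage $2k$ an error-free true heterozygote is called with
probability $\binom{2k}{k}/2^{2k}$ (≈ 0.176 at coverage 20). All
downstream statistics are therefore built as **ratios** between an
offspring and its mother scanned at identical settings, in which the
sensitivity cancels.

Because the simulator generates pileups only at maternal heterozygous
sites (there are no collapsed repeats to guard against in simulation),
the pipeline default is `even_split` mode, which keeps every
even-coverage site and roughly doubles the usable site count;
`mean_coverage` remains the default for single-sample scans of real
pileups and is what the duplication-versus-mother contrasts use.

## The classifier

`infer_mechanism()` computes, for one offspring against its mother:

* `retained_fraction`: offspring ÷ maternal heterozygous-call counts
  over jointly considered sites;
* `interspersion`: the fraction of windows, among windows where the
  mother has calls, in which the offspring reaches ≥ 50% of her count
  (a formalisation of "retained blocks look like the mother locally");
* a `centromere_profile`: per-bin retention by normalized centromere
  distance, plus a site-level Spearman trend between distance and the
  offspring call indicator (binning to ten points would throw away most
  of the power, so the trend is computed on sites; the bin-level rank
  correlation is still reported for plotting);
* a retention-deficit z-score: how far the retention ratio falls below
  1 in units of its Poisson standard error.

`classify_mechanism()` then applies, in order: the duplication box
(retention and interspersion ≤ 0.05); a material spatial trend
(|rho| ≥ 0.02 and p ≤ 1e-3), whose sign separates central from
terminal; the sexual box (both statistics ≥ 0.8) guarded by the deficit
test (a ratio more than 3 SE below 1 is incompatible with sexual
reproduction even when the spatial trend happens to be flat); and
finally the pericentromeric decision — proximal-bin retention ≥ 0.5 is
central automixis, below it terminal. The ordering matters: at one to
two crossovers per chromosome, central automixis retains 70–90% of
maternal heterozygosity genome-wide and would otherwise sit inside a
naive "looks sexual" box. All thresholds are exposed via
`thresholds = list(...)`.

Without centromere coordinates (the realistic situation for
scaffold-level assemblies) `use_profile = FALSE` reduces the rule to the
two boxes plus `indeterminate`; duplication — the mechanism actually at
issue for whiptail lizards — is still fully separable this way.

## Simulated study conditions

The default pipeline configuration (`default_pipeline_config()`) fixes
the synthetic study conditions:

| parameter | default | why |
|---|---|---|
| karyotype | 23 telocentric chromosomes × 1 Mb | chromosome count of the reference karyotype, lengths scaled down for desk-scale runs; macrochromosomes are acro/telocentric |
| `het_density` | 1e-3 /bp | ~23,000 maternal heterozygous sites, the order observed in sexually produced mothers |
| `crossover_rate` | 2 per arm (obligate chiasma) | one to two effective crossovers per chromosome |
| `mean_coverage` | 18.37 | the WGS cohort's mean coverage |
| `error_rate` | 1e-3 | post-filter short-read miscall rate |
| windows | 100 kb tumbling | ~19 calls per maternal window, enough for a stable interspersion ratio |

The chromosome *number* matters more than total length: with few
chromosomes, an individual central-automixis meiosis can by chance
retain essentially all maternal heterozygosity (each chromosome's
retention is an all-or-large-block random variable), making it
statistically indistinguishable from a sexual offspring. Averaging over
23 independent meioses concentrates the retention statistics enough for
≥ 95% per-class recall, which the test suite checks on 4 × 200
simulated cohorts.

What the generator deliberately does *not* emulate: collapsed repeats
and paralogy (the reason for the mean-coverage guard in real data),
gene conversion, crossover interference, meiotic drive, reference bias,
and mapping artifacts. Passing tests therefore demonstrate the
statistical machinery under the stated meiosis model, not robustness to
every failure mode of real alignments.

## Microsatellite parentage

`bin_alleles()` merges allele sizes within a comparison set by
single-linkage with a 1-bp link distance (±1 bp differences are standard
fragment-analysis binning artifacts), capped at a 2-bp cluster width so
that genuinely distinct alleles — which differ by at least one 2-bp
repeat unit — are not chained together. `classify_offspring()` performs
exclusion-based parentage: FP requires homozygosity at every scored
locus, full maternal consistency, and exclusion of every candidate
father at ≥ 1 locus (configurable); loci where mother and a male share
the offspring's allele are scored uninformative, not exclusionary.

With noisy sizes, comparisons can additionally be made tolerance-aware
(`tolerance_bp = 1`), which absorbs chains the capped merge could not
resolve (e.g. an unrelated allele sitting 1 bp from a mother–offspring
cluster). At a 5% per-observation artifact rate this recovers ≥ 99% of
true parthenogens; by ~10% double-artifact collisions (two independent
±1 shifts producing a 2-bp gap, the size of a real repeat step) push
recovery to ~98% — an inherent resolution limit of 1-bp tolerance
scoring, stated here rather than hidden.

## Population screen and mixoploidy

`rosner_esd()` implements the generalized extreme Studentized deviate
test with the Student-t critical-value formula
$\lambda_i = t_{p,\nu}(n-i)/\sqrt{(\nu+t^2)(n-i+1)}$,
$\nu = n-i-1$, $p = 1-\alpha/(2(n-i+1))$; the implementation reproduces
the standard reference values (λ = 3.159, 3.151, 3.144 for n = 54,
α = 0.05) and is calibrated under a normal null (the ≥ 1-outlier rate
at n = 75, k = 5 is within Monte-Carlo error of α). The screen runs
within species on log-transformed percent heterozygosity (the quantity
is strongly right-skewed; zeros are replaced by half the smallest
positive value, with a warning) and, because the ESD statistic is
two-sided while parthenogens are specifically *low*-heterozygosity
outliers, flagged individuals are post-filtered to the low side.

`count_fractions()` and `detect_ploidy_peaks()` quantify mixoploidy —
the hallmark downstream prediction of haploid-initiated development —
from erythrocyte class counts and from DNA-content histograms
(Freedman–Diaconis binning, smoothed local maxima with relative-distance
non-maximum suppression, nearest-peak event assignment; a haploid
population is called when a peak sits within ±15% of half the diploid
reference intensity, a window wide enough for typical staining CV).
No mixture model is fitted by default; for two well-separated Gaussian
classes histogram peaks recover the haploid proportion to within ±0.02
at flow-cytometry event counts (~44,000).

## Numerical and design notes

* Coordinates are 0-based, half-open everywhere (BED conventions).
* All randomness flows through explicit `seed` arguments; the pipeline
  derives per-individual seeds from one master seed, restores the
  session RNG state afterwards, and stamps outputs with the seed and a
  config hash. Identical seed and config give byte-identical outputs.
* Tetrad chromatids are segment step-functions; crossovers are applied
  proximal-to-distal within each arm, which is equivalent to the
  physical exchange of telomere-side segments.
* `rosner_esd()` refuses n ≤ k+1 and zero-variance input rather than
  returning NaN statistics.
* Ties in allele-size binning resolve to the smallest modal size;
  chains wider than twice the tolerance are left unmerged with a
  warning rather than collapsed.
* Problem sizes in the test suite (10,000 meioses per oracle
  comparison, 4 × 200 cohorts, 10,000 ESD null replicates, 44,000
  flow events) were chosen so each property is measured well inside its
  Monte-Carlo tolerance while the whole suite stays a few minutes long.

## Limitations

* Real-data spatial classification requires centromere coordinates,
  which scaffold-level assemblies usually lack; the interspersion route
  (and the duplication call specifically) is the one designed to work
  without them.
* The oracle enumerates at most three crossovers exactly; beyond that,
  validation falls back to Monte Carlo.
* The paper-scale population screen statistics (e.g. a specific R and λ
  for one species) depend on per-individual tables not shipped here;
  the screen is validated on calibration and planted-outlier behaviour
  instead.
* Mixoploid development is represented only at the observable level
  (class counts, DNA-content events), not as a cell-lineage model.
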