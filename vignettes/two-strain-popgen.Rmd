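---
title: "Methods: two-strain population genomics with fawpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-strain population genomics with fawpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fawpopgen)
```

## The system and the data model

Fall armyworm in North America is a dyad of two reproductively
semi-isolated strains (C and R) whose genetic differentiation is
concentrated on the Z chromosome. Trap-collected moths are male and
therefore ZZ, so every chromosome — including the Z, stored as
chromosome "31" — is treated as ordinary diploid throughout.

`StrainGenotypes` extends `RangedSummarizedExperiment`: rows are sites
(a `GRanges` carrying REF/ALT and a multi-allelic flag), columns are
samples, and the assays are the dosage matrix `GT` (0/1/2 copies of the
alternate allele, `NA` missing) plus per-genotype `DP` and `GQ`. All
statistics use pairwise deletion of missing genotypes; `naiveImpute()`
exists to make that policy explicit (or to fill with the per-site modal
dosage, ties broken toward the lower dosage), and deliberately does not
attempt haplotype-model imputation: a statistical imputer would inject
model assumptions into every downstream denominator, whereas explicit
denominators keep them honest.

## Filters

`filterSiteQuality()` masks genotypes with DP < 6 or GQ < 10 (both
per-genotype quantities), then removes sites whose missing fraction
*after* masking exceeds 0.5. Ties at exactly 50% are retained — the rule
is "more than half missing". Masking-before-counting is a declared
choice; the alternative order is not distinguishable from published
descriptions of this filter chain. `filterBiallelicMaf()` keeps sites
with exactly one ALT allele and global minor-allele frequency ≥ 0.01
computed over all samples (hybrids included — hybrids are only excluded
later, from the between-strain comparisons). No filter ever alters a
retained genotype except the DP/GQ masking itself.

## Windowed statistics

All "sliding" windows are non-overlapping tiles (step = width) anchored
at position 0 and half-open `[start, end)` — the default behaviour of
the windowing tools this workflow mirrors. Defaults: 10 kb for Fst and
Dxy, 5 kb for π and Tajima's D.

**Weir–Cockerham Fst.** Per site the 1984 variance components a, b, c
are computed from the two groups' sample sizes, allele frequencies and
observed heterozygosities; sites where a+b+c = 0 (or a group has fewer
than two genotyped individuals) are skipped and counted. Window and
global estimates are ratios of sums, Σa/Σ(a+b+c) — never means of
per-site ratios, which would weight noisy singletons equally with
well-genotyped sites.

**π and Dxy.** Both use explicit denominators so that invariant
genotyped sites and missing data are handled honestly: per site,
π contributes diffs = c₀c₁ and comps = m(m−1)/2 over the m observed
alleles; Dxy contributes diffs = c₁ᴬc₀ᴮ + c₀ᴬc₁ᴮ and comps = mᴬmᴮ.
A window's value is Σdiffs/Σcomps, missing when no comparisons exist.
Dxy first drops sites with more than 20% missing genotypes across the
two groups.

**Tajima's D.** The 1989 formula with the standard constants. Missing
data make the observed allele number site-specific while the constants
need a single n; the window's effective n is the median observed allele
count across its segregating sites. Windows with S = 0, effective
n < 4, or a non-positive variance estimate are reported missing.

**LD.** r² is the squared Pearson correlation of genotype dosages
(composite LD) because genotypes are unphased; pairs with a monomorphic
member are skipped. `ldDecay()` bins pairs at the eleven nominal
distances 100 bp – 75 kb, each ± 50 bp, and reports mean, median and
pair counts per bin — both mean and median are emitted because decay
curves are conventionally plotted as means while single-distance
summaries are often medians.

## Genomic islands of divergence

`islandScan()` smooths windowed Dxy along one chromosome with a
Nadaraya–Watson Gaussian kernel (default bandwidth 50 kb — wide enough
to bridge single-window noise on a 10 kb grid, narrow enough to leave
sub-megabase structure visible; it is a configurable display/test
parameter, and island widths depend on it). The null reorders the
window values over the same positions `n_perm` times (whole-chromosome
permutation, not blocks) and smooths each permutation identically; the
threshold is the single most extreme smoothed value across all
positions of all permutations — the most conservative reading of a
permutation max-null — and islands are maximal runs of windows whose
observed smoothed value exceeds it. By construction the threshold is
monotone in `n_perm` and the test is invariant to adding a constant to
all values; under exchangeability the chance of any island is about
1/(n_perm+1), which the test suite checks empirically at n_perm = 200
over 200 replicates.

## Selective sweeps

**Background SFS.** `backgroundSFS()` projects every site down to a
common allele number (the cohort median) by hypergeometric projection
and folds the spectrum (ancestral states are unknown in a VCF). The
monomorphic class is included by default: the scan operates on the full
SNP set restricted to one population, where fixed differences and swept
sites are monomorphic *within* the group — precisely the sites that
carry sweep evidence. The classical polymorphic-only spectrum is
available with `include_monomorphic = FALSE`.

**CLR scan.** At each of `floor(length/5 kb)` grid points, each site at
distance d escapes the sweep with probability 1 − e^{−αd}; of n
lineages, Binomial(n, p_e) escape and retain the background spectrum
(subsampled hypergeometrically from a symmetrised pre-sweep count),
while the hitchhiked lineages all carry the swept haplotype's allele
(derived with probability i/n given pre-sweep count i) — a star-tree
approximation. The composite log-likelihood ratio against the
background spectrum is maximised over a fixed 40-point logarithmic α
ladder (10⁻⁷–10⁻¹ per bp) and floored at 0; a fixed ladder is
deterministic and testable where a continuous optimiser is neither. At
p_e = 1 the model reproduces the background exactly, so the log-ratio
of distant sites is identically zero; the compiled kernel exploits this
by restricting each sum to sites within α·d < −log(0.5/511), which is
exact under the 512-bin p_e quantisation. Sites whose observed allele
number differs from the projection size enter the scan with their count
rescaled (`round(b·n/m)`); the full projection is reserved for the
spectrum estimate itself.

**Outliers and refinement.** Outliers are grid points at or above the
99.99th percentile of CLR values pooled genome-wide per population
(pooling scope is switchable to per-chromosome; genome-wide is the
stricter reading of "any chromosomal window"). A degenerate all-equal
grid reports no outliers. `refineSweepRegion()` rescans the outlier's
chromosome at 1 kb spacing and returns the maximal run of consecutive
fine windows containing the outlier with CLR at or above that
chromosome's 99th fine-grid percentile; an outlier that is not elevated
on the fine grid yields an empty region rather than a fabricated one.

**ω statistic.** For each 5 kb evaluation window the SNPs are split at
every possible point into left/right blocks; ω is the ratio of average
within-block r² to average between-block r², maximised over splits and
block extents. `minwin`/`maxwin` are interpreted in bp (their units are
not fixed by the tools this mirrors): each block may span at most
`maxwin` and the two blocks together at least `minwin`. A zero
between-block r² sum yields the declared cap (default 100) with a flag.
Because strain-level linkage makes the Z one giant LD block, the ω scan
is restricted to autosomes — on the Z it would flag the entire
chromosome. ω outliers are reported by rank; no formal threshold is
defined for this scan, matching how such outliers are normally read.
Dense windows are evenly thinned to `max_snps` (default 60) SNPs before
the O(W³) maximisation.

## PCA and group Fst

`pattersonNormalize()` uses the shrunk frequency estimate
p̂ = (1+Σg)/(2+2n) and scales by √(p̂(1−p̂)); missing entries become 0
after centring (the standard treatment for incomplete genotype
matrices) and monomorphic sites are dropped. `genotypePca()`
eigendecomposes the sample covariance of that matrix on the full,
autosomal or Z-only data; component signs are arbitrary and tests are
sign-agnostic. Tracy–Widom component significance is out of scope.
`pairwiseGroupFst()` applies the weighted Weir–Cockerham estimator to
every pair of a-priori groups (strain, flyway, strain × flyway).

## The simulator: what it emulates, and what it does not

`simulateCohort()` is a Balding–Nichols generator: ancestral frequency
p per site, strain frequencies Beta(p(1−F)/F, (1−p)(1−F)/F) with
F = 0.671 on the Z and 0.086 on the autosomes (the genome-wide
strain-differentiation estimates for this system), C-strain flyway
subpopulations drawn around the strain frequency at F = 0.047, and
binomial diploid genotypes. Balding–Nichols was chosen because the
weighted Weir–Cockerham estimator consistently recovers its F
parameter, which the test suite verifies at F ∈ {0.05, 0.1, 0.3,
0.671} within ±10% from 50,000 sites and 100 diploids per strain (with
sub-structure off — the recovery property concerns the plain
two-population model; the sub-structure default adds ~0.005–0.007 of
between-strain differentiation on top of F).

Hybrids are F1-like — one haplotype drawn from each strain's frequency
— because the strain caller keys on marker heterozygosity; backcross
gradations are out of scope. Four diagnostic markers on the Z are
forced to fixed differences (C carries REF), so pure samples are
homozygous and F1 hybrids heterozygous at markers by construction.
`degradeGenotypes()` masks genotypes i.i.d., and draws
DP ~ Poisson(100) and GQ ~ N(60, 15) clamped to [0, 99] — the depth
reflects the high-coverage sequencing this workflow assumes, and the
defaults leave realistic tails below the DP 6 / GQ 10 cutoffs.
`injectSweep()` drives the target group's minor allele out at each site
with probability e^{−d/strength}, recording
center ± 3·strength as the true swept interval.

Two ancestral-frequency models are provided. `spectrum = "uniform"`
draws p ~ U(0.05, 0.95): convenient for differentiation work, but it
is SFS-agnostic — windowed Tajima's D is strongly positive under it
regardless of demography, because intermediate frequencies dominate.
`spectrum = "neutral"` draws p with the standard-neutral 1/p density
(and, at zero differentiation, assigns per-site minor counts with
P(j) ∝ 1/j to random haplotypes, which makes E[π] = E[S]/a₁ hold
exactly). The neutral spectrum is the right background for anything
that reads Tajima's D or the SFS: the neutrality calibration (median
windowed D within (−0.5, 0.5)) and the pooled-cohort contrast — pooling
two diverged strains converts rare variants into
intermediate-frequency Z variants, raising Z-linked D and 10 kb r²
above the autosomes, the qualitative signature of a two-haplotype Z.
That contrast is invisible under the uniform spectrum, whose baseline
D swamps it.

What the generator does **not** emulate: coalescent genealogies (no
recombination maps, no demography, no LD beyond what strain and
subpopulation mixture induce), read-level error, indels, linked
selection outside the injected hard sweeps, and backcrossed hybrids.
Passing tests therefore demonstrate estimator correctness and
procedure behaviour under a controlled generative model — not that the
pipeline's numerical output on real armyworm data would match any
particular published value.

## Numerical choices and degenerate inputs

- Dosage conversion treats any genotype containing "." as missing;
  multi-allelic records count non-reference alleles and are flagged,
  then removed by the biallelic filter.
- Percentages in composition tables are rounded half-up — the
  convention that reproduces printed integer compositions.
- Discordant homozygous marker profiles (some C-hom, some R-hom, no
  het) are labelled `unknown` with an audit flag, not `hybrid`:
  heterozygosity is the hybrid signal, and promoting discordance would
  inflate hybrid counts.
- Degenerate statistics return `NA` (never 0): windows without
  comparisons, D with S = 0 or n < 4, r² with a monomorphic member.
- The CLR lookup floors probabilities at 10⁻¹², and classes with zero
  background mass carry zero log-ratio rather than ±∞.
- Seeds: every stochastic entry point takes an explicit seed and is
  byte-reproducible; the pipeline manifest hashes outputs so reruns can
  be verified.

## Problem sizes

The test suite and acceptance script run, by design, on scaled-down
cohorts chosen to exercise every code path with stable statistics:
50,000 sites × 200 diploids for Fst recovery; a 1.5 Mb chromosome with
6,000 sites (300 windows) for the neutrality calibration; 200
replicates at n_perm = 200 for the island false-positive rate; twenty
10 Mb single-chromosome replicates at 8,000 sites (roughly one SNP per
1.2 kb, conservative relative to high-coverage cohorts of this
species) for sweep localisation; and toy matrices of ≤ 6 samples for
the brute-force oracle comparisons.

## Known limitations

- The CLR model is a star-tree approximation with a fixed α ladder;
  it localises and ranks sweeps but its absolute CLR values are not
  calibrated likelihood ratios against a coalescent null.
- The ω maximisation is O(W³) per window and relies on thinning in
  dense windows.
- Tajima's D with heavy, non-uniform missingness leans on the single
  effective-n approximation.
- The island test's bandwidth is a genuine free parameter; island
  boundaries (though not their existence under the null) move with it.
- VCF output is one-ALT-per-record and drops INFO fields; the reader
  flags but does not decompose multi-allelic records.
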