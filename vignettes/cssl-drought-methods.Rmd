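---
title: "Methods: drought-resistance phenomics and QTL mapping in a cotton CSSL panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-resistance phenomics and QTL mapping in a cotton CSSL panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cssldrought` analyzes drought resistance in a chromosome-segment
substitution line (CSSL) population: an interspecific cotton panel in
which each line carries one or a few homozygous *G. barbadense* donor
segments in an otherwise *G. hirsutum* recurrent background. This
vignette is the package's account of its models, its tunable
parameters, and the choices made where the design was genuinely open.

## Phenotype model and BLUPs

Raw observations are indexed by line, trait, condition (control vs
drought), year and replicate. For each trait-by-condition cell,
`fit_blup()` fits

$$y_{ijk} = \mu + \text{year}_j + \text{rep}_{k(j)} + u_i +
\varepsilon_{ijk}, \qquad u_i \sim N(0, \sigma_g^2),\;
\varepsilon \sim N(0, \sigma_e^2),$$

with year and replicate-within-year fixed and the line effect random.
Variance components are estimated by REML through an
expectation–maximization iteration on the mixed-model equations.
Because the design has a single random factor, Z'Z is diagonal and the
M-step is closed-form after absorbing the random effects, which makes
the iteration stable in the two degenerate limits the tests exercise:
identical replicates (no shrinkage; BLUP = line mean) and zero genetic
variance (full shrinkage to the grand mean), where general-purpose
optimizers tend to warn or fail. The convergence tolerance is 1e-8
(relative, on the variance components), capped at 500 iterations. The
reported per-line value is the average fixed-effect prediction over the
observed design plus the line BLUP; the tests verify it against both a
direct GLS solve at the REML optimum and an independent `lme4` fit.

Lines without observations in a cell are reported `NA`, never imputed.

## DRC, MFVD, grading

The drought-resistance coefficient is `DRC = drought BLUP / control
BLUP` per line and trait (`compute_drc()`); cells with non-positive
control values are flagged undefined rather than zeroed. Computing DRC
from condition-wise BLUPs (rather than per-year means) follows from
fitting BLUPs first; a per-year DRC can be had by filtering the
observation table to one year before `blup_table()`.

The composite score (`compute_mfvd()`) min–max rescales each basis
trait's DRC over the population — membership $(x - \min)/(\max - \min)$
for higher-better traits, mirrored for lower-better — and averages over
the eight basis traits: yield (BW, LW, LP, EBN) and fiber quality
(FUHML, FS, MV, FU), equally weighted. This is the conventional
membership-function construction; the only genuinely open orientation
is micronaire (MV), whose quality optimum is a band rather than a
monotone direction. The default treats MV higher-better on the DRC
scale and exposes `orientation = c(MV = "lower")` for the opposite
reading. A trait constant across the population would make the
membership 0/0; it is set to 0.5 for every line with a warning, which
leaves the MFVD mean unbiased while flagging the degenerate input.

`grade_lines()` bands the MFVD distribution into five levels at four
ascending cutoffs, half-open and lower-inclusive from above (grade V
iff MFVD ≥ c4). Published studies report level counts but not cutoffs;
the default is mean ± 1.5 and ± 0.5 standard deviations, which on a
normal score yields ≈ 6.7 / 24.2 / 38.3 / 24.2 / 6.7% — the shape, not
the exact counts, of a typical five-level grading. The exact printed
counts of any particular study are not a reproduction target.

The trait correlation network uses Pearson correlations over
pairwise-complete lines with the significance rule p < 0.05 and
|r| > 0.1. The threshold is read on the signed coefficient: the
conventional notation "R² < −0.1" cannot refer to a squared quantity.

## Mixed-model association scan

After filtering (retain MAF > 0.05 and missingness < 0.5 — note in a
CSSL panel the donor frequency at a marker is roughly the panel's
donor-coverage fraction there, so most markers sit near this boundary
and the filter removes the majority, as it does in real resequenced
panels), `compute_kinship()` builds the VanRaden centered cross-product
with mean imputation confined to the kinship estimate.

`mlm_scan()` fits, per marker, $y = \mu + x\beta + u + e$ with
$u \sim N(0, \sigma_g^2 K)$. The variance ratio is profiled once on the
marker-free null by REML in the eigenbasis of K — a 64-point grid on
$\log\gamma \in [-10, 10]$ refined by golden-section/Brent search to
1e-6 — and held fixed across markers (the standard
population-parameters-previously-determined speed/accuracy trade;
`per_marker_reml = TRUE` re-profiles per marker on small panels).
Each marker is then a 2-parameter GLS with a two-sided Wald t-test at
residual degrees of freedom. Missing dosages are dropped pairwise per
marker, implemented exactly: the GLS quadratic forms on the observed
subset are obtained from the precomputed full-panel $V^{-1}$ by a block
downdate over the (few) missing lines, which the tests verify against
explicit `solve(V[S, S])` fits to 1e-8. Markers constant after
missing-drop are skipped with a reason; perfect fits are reported at
p = 1e-300 rather than 0 to keep p in (0, 1].

Thresholds are suggestive 1/M and significant 0.05/M for M tested
markers. Significant markers closer than 1 Mb on a chromosome merge
into one QTL interval whose minimum-p marker is the highlighted SNP;
the merge distance is configurable since published reports give peaks
and intervals but no merge rule. Candidate intervals are ±300 kb
around the highlighted SNP, clipped to the chromosome and united with
the containing LD block when one exists. LD blocks are greedy runs of
markers with r² ≥ 0.8 against the block seed — block-definition tools
differ (Gabriel-type confidence intervals vs r²); the r²-based rule is
the one documented and tested here.

No principal-component covariates are added beyond kinship: in a
bi-parental CSSL panel there is no population structure other than the
segment-sharing that K captures.

## Bin-map linkage scan

`build_bin_map()` merges consecutive markers whose dosage columns agree
at every jointly observed line (missing entries are wildcards; the bin
genotype is the majority code over member markers), with bin boundaries
at midpoints between adjacent distinct markers. On a CSSL panel bins
correspond to the segments between introgression breakpoints.

`rstep_lrt_add_scan()` is a reimplementation of the stepwise
likelihood-ratio additive scan used for substitution-line maps (the
original software's internals are not published, so this is the
documented idea, not a bit-compatible clone): forward–backward stepwise
selection of cofactor bins by partial F-test (p_enter 0.01, p_exit
0.02, capped at 15 cofactors), then a per-bin Gaussian LRT with
cofactors within 5 Mb of the tested bin excluded — the standard
composite-interval practice. LOD = LRT/(2 ln 10); the additive effect
is half the donor-vs-recurrent contrast (dominance is not modeled, per
the additive design of the method); PVE is the R² increment. The LOD
call threshold defaults to a permissive 2.5, consistent with reported
substitution-line QTL in the low-LOD range, and is configurable.

## BSA ΔSNP-index

Pools are the top and bottom 30 lines by MFVD (ties broken by line id,
deterministically). The per-site SNP-index of a pool is its donor-read
fraction at parent-discordant homozygous sites with per-pool depth
≥ 10; Δ = index(resistant) − index(sensitive). Windows of 1.5 Mb
advance by 100 kb (the window size is conventional; the step is a
design choice giving 15× overlap).

The confidence band is Monte-Carlo under a CSSL-aware null, the main
bespoke modeling decision of the package:

1. at each site the pool's composition is resampled at the *observed
   population donor frequency* — low and locus-specific in a CSSL
   panel — not at the F2 expectation of 0.5;
2. because substitution lines are near-fixed, a pool of k lines
   carries k independent chromosome draws, not 2k; the null therefore
   resamples k homozygous lines (`inbred = TRUE`). The literal
   2k-chromosome null under-disperses by about √2 in the composition
   term and its 99% band is exceeded ~4% of the time instead of ~1%;
3. reads are then binomial at the realized pool frequency and the
   site's depth.

Simulation is tabulated over (frequency, depth) cells — frequency bin
0.005, chosen to resolve panel frequencies of 0.02–0.1; depth bin 10 —
with 10,000 draws per cell, and band quantiles use the inverse
empirical CDF (type 1): interpolated quantiles are anti-conservative on
the discrete delta support. Under independent per-site null draws the
measured exceedance of the 99% band is 0.9–1.2%. Note that a single
fixed pool shares its composition noise across the whole genome, so the
realized exceedance of any one study fluctuates around 1% (measured
0.4–1.5% across pool draws); the calibration statement is marginal over
pools.

Windows whose |mean Δ| exceeds the averaged band merge into intervals,
tolerating one sub-threshold gap window for robustness to sparse sites.
At the package's desk-scale marker density (~1 site per 270 kb) a
window holds 4–6 sites, so the pipeline default for the minimum sites
per window is 3; the function default of 10 suits sequencing-density
data.

## Integration and pyramiding

QTL are named `q.<TRAIT>.<Chr>.<k>` with k the positional ordinal per
trait and chromosome. Co-localization is single-linkage grouping of
intervals overlapping by ≥ 1 bp (the most permissive reading of
"co-located"; `min_overlap_bp` is configurable), computed with
IRanges overlaps plus union-find and tested against a brute-force
transitive closure. Haplotypes are called at the GWAS highlighted SNP
(downstream haplotype work anchors on GWAS peaks because linkage and
BSA intervals are too wide to pick a single SNP); for non-GWAS records
the marker nearest the peak is used. The drought-resistant haplotype at
a QTL is the group (donor vs recurrent homozygotes; hets and unknowns
excluded) with the larger mean of the QTL's DRC trait, contrasted by
Welch's t-test — group sizes and variances are unequal by construction
in a CSSL panel. The pyramiding analysis counts resistant haplotypes
per line and reports the Pearson correlation of that count with MFVD.

## The synthetic study generator

The generator exists so that every stage is testable against known
truth; its defaults are the package's study conditions, set once:

- **Shape.** 319 lines, 26 chromosomes with approximate tetraploid
  cotton lengths (~2.1 Gb), 400 markers per chromosome (~10,400 total),
  2 conditions × 2 years × 2 replicates, 14 traits. Trait-by-condition
  means mirror a two-year cotton drought trial (e.g. PH 65.5 → 37.5 cm,
  EBN 5.54 → 3.00, FS 25.99 → 26.30 cN/tex).
- **Segments.** Per line, a Poisson(5) number of donor segments with
  exponential lengths (mean 18 Mb, truncated 2–40 Mb), placed uniformly
  without overlap, under a 10% donor-genome cap — a few percent donor
  genome per line, the advanced-backcross expectation. Dosage defaults
  to homozygous donor (`het_prob = 0`). Segment endpoints are free and
  snap to the marker grid through marker membership. Missing genotypes
  are injected at 1% to exercise the filters.
- **Anchors.** Each planted QTL additionally receives ~30 carrier lines
  with independently jittered segments covering it. Real CSSL panels
  are likewise enriched for recurring introgressions; without anchors a
  uniformly random panel leaves nearly every marker below the 5% MAF
  filter (as most SNPs are in real panels), and a locus nobody carries
  is unmappable by any method.
- **QTL.** Five loci, each affecting two MFVD basis traits only under
  drought, with effects of +8% of the trait's control mean for donor
  homozygotes — a DRC shift of ~0.08, i.e. ~15–25% of the DRC variance
  at ~30 carriers. These are deliberately major-effect,
  condition-specific loci: the study conditions ask every mapping
  strategy to see them.
- **Variances.** Genetic, year, replicate and residual components at
  CVs of 3 / 1.5 / 0.8 / 3% of each condition mean, drawn independently
  per condition. Realized line-mean heritability then matches
  σ²g/(σ²g + σ²e/4) within Monte-Carlo error, which the tests check.
- **Pools.** Poisson read depth (mean 50) and binomial donor reads at
  the pool frequency — the same model the confidence-band simulator
  assumes.

What the generator does *not* emulate: linkage between segments arising
from shared backcross pedigree, genotyping error other than
missingness, residual heterozygosity beyond a constant rate,
non-Gaussian trait noise, genotype-by-year interaction, and reference
or alignment artifacts in read counts. Passing tests therefore
demonstrate the pipeline's correctness and calibration under its stated
model, not robustness to every failure mode of field data.

## Problem sizes and determinism

The default study (319 × 10,400, nine scanned phenotypes) runs the full
pipeline in about a minute on one CPU; the test suite adds a null
calibration scan at 300 lines × 5,000 markers and a band-coverage check
at 10,000 sims per cell, and completes in under two minutes. The
linkage permutation-null property is exercised at a reduced scale (the
two-chromosome, 120-line fixture with 60 permutations), a size chosen
to keep the property informative at interactive runtimes.

One master seed fans out deterministically to per-stage child seeds, so
identical configurations produce byte-identical output trees (verified
by checksum in the tests). All coordinates are 1-based inclusive
internally; BED-like outputs are 0-based half-open, converted and
round-trip-tested both ways.

## Known limitations

- The MLM scan holds the variance ratio fixed across markers; for very
  large single-marker effects the exact per-marker REML flag is the
  more conservative choice.
- The greedy r² block rule is order-dependent (seeded at the leftmost
  unassigned marker) and is not a Gabriel-interval implementation.
- The stepwise scan caps cofactors at 15; panels with many strong,
  well-separated QTL may warrant raising it.
- The BSA band conditions on the observed population frequency as if
  known; at very low carrier counts the plug-in estimate is itself
  noisy, which slightly widens realized exceedance around the nominal
  level.
- `fit_blup()` supports the stated design (year + rep within year);
  other field designs need the model extended.
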