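# cssldrought

Drought-resistance dissection of an interspecific cotton
chromosome-segment substitution line (CSSL) population, as a tested,
reusable R pipeline.

CSSL panels carry short *Gossypium barbadense* donor segments in a
*G. hirsutum* recurrent background, so a drought-responsive locus shows
up as a segment whose carriers lose less yield or fiber quality under
water stress. `cssldrought` implements the full chain of analyses such a
study needs, for breeders and quantitative geneticists who want each
stage reproducible and testable on data with known ground truth:

- **Phenomics.** Multi-year, replicated trait observations are reduced
  to per-line BLUPs from the mixed model
  *y = μ + year + rep(year) + line + ε* (line random, REML). Drought
  response per line and trait is the drought-resistance coefficient
  **DRC = value(drought)/value(control)**, and the composite score is
  the membership function value of drought resistance,
  **MFVD = mean over basis traits of (DRC − min)/(max − min)**, banded
  into five grades (I sensitive … V tolerant). Pearson correlation
  networks, CV/percent-change summaries, and the physiology formulas
  REC = C1/C2 × 100, MDA = 25.8·ΔA/FW and 2^−ΔΔCt are included.
- **Mixed-linear-model GWAS.** MAF/missingness filtering, VanRaden
  kinship, and an EMMA-style scan: the variance ratio σ²g/σ²e is
  profiled once on the null model by REML on the spectral decomposition
  of K, then every marker is tested by generalized least squares with a
  Wald t-test. Thresholds follow the 1/M (suggestive) and 0.05/M
  (significant) convention. LD blocks (greedy r² ≥ 0.8) and ±300 kb
  candidate intervals around peak SNPs complete the stage.
- **Bin-map linkage scan.** Introgression bins from identical marker
  columns, then a stepwise-cofactor likelihood-ratio additive scan:
  forward–backward partial-F selection of background bins, per-bin LRT
  with cofactors excluded within 5 Mb, LOD = LRT/(2 ln 10).
- **BSA ΔSNP-index.** MFVD-ranked 30/30 extreme pools, per-site
  SNP-index (donor-read fraction) and Δ = index(resistant) −
  index(sensitive), 1.5 Mb sliding windows, and Monte-Carlo 99%
  confidence bands under a CSSL-aware null that resamples homozygous
  pool members at each locus's *observed* population donor frequency
  (not the F2 assumption of 0.5).
- **Integration.** QTL naming (`q.<TRAIT>.<Chr>.<k>`), single-linkage
  co-localization across the three methods, haplotype calls
  (hap_donor / hap_recurrent) at peak SNPs, selection of the
  drought-resistant haplotype by DRC contrast (Welch test), and a
  pyramiding analysis correlating each line's resistant-locus count
  with its MFVD.
- **Synthetic studies.** A generator for complete CSSL studies —
  segment structure, condition-dependent QTL effects, multi-year
  phenotypes, pooled read depths — with the ground truth retained, so
  every downstream stage is testable without external data.

## Worked example

```r
library(cssldrought)

bundle <- run_pipeline(study_config(seed = 1))
#> [cssldrought] simulated 319 lines x 10400 markers, 5 planted QTL
#> [cssldrought] phenomics done: 319 graded lines, 91 network edges
#> [cssldrought] GWAS: 3740 markers scanned, 15 QTL at p < 0.000267
#> [cssldrought] linkage: 2916 bins, 62 QTL at LOD >= 2.5
#> [cssldrought] BSA: 10400 sites, 22010 windows, 10 intervals
#> [cssldrought] integration: 47 groups (5 multi-method); pyramiding r = 0.74
```

The default study plants five condition-specific QTL (each affecting
two MFVD basis traits only under drought). All five are recovered by
GWAS and linkage and four by BSA, each within 2 Mb of truth:

```r
with(bundle$recovery, tapply(recovered, method, sum))
#>     bsa    gwas linkage
#>       4       5       5

bundle$pyramiding$r      # resistant-locus count vs MFVD
#> [1] 0.7350936
```

`91` network edges is `choose(14, 2)` — one per unordered trait pair.
The `15 QTL at p < 2.7e-4` line reports the suggestive threshold 1/M
for the M = 3740 markers that survive filtering; on a 1.3M-SNP panel
the same rule gives `association_thresholds(1309780)` = 7.63e-7 /
3.82e-8. The pyramiding correlation says lines stacking more resistant
haplotypes score higher MFVD, the marker-assisted selection signal the
analysis is after.

Individual stages are plain functions on plain tables
(`fit_blup`, `compute_drc`, `compute_mfvd`, `mlm_scan`,
`rstep_lrt_add_scan`, `snp_index`, `confidence_bands`, `colocalize`,
`pyramiding_analysis`, …); see the methods vignette
(`vignettes/cssl-drought-methods.Rmd`) for the models and the design
choices behind them.

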