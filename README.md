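# ewasmr

Does blood DNA methylation *mediate* the effect of oropharyngeal-cancer
prognostic factors — smoking, alcohol intake, HPV16 E6 serostatus — on
survival around three years after diagnosis? `ewasmr` implements the full
analysis chain for that question as a tested, reusable R pipeline, and
ships a synthetic-cohort generator with known ground truth so every stage
can be calibrated and its recovery properties measured.

The chain, for each prognostic factor:

1. **Single-site EWAS.** Per CpG, OLS of methylation beta (in \[0, 1\]) on
   the exposure, adjusting for age, sex, the other prognostic factors and
   surrogate variables (two-step residual-SVD SVA with permutation-based
   selection of K). Survival is analysed per CpG with Cox
   proportional-hazards models (Efron ties): model 1 adjusts for age, sex
   and SVs; model 2 additionally for the three exposures. Genome-wide
   significance uses the Bonferroni constant `0.05 / 862491 = 5.7e-8`
   (printed-mantissa truncation) with `2.4e-7` as the suggestive level.
2. **DMR calling.** Candidate regions are maximal runs of nearby CpGs
   (gap ≤ 500 bp) with same-sign effects at P < 0.05. Every sub-window is
   scored by generalized least squares under the residualised CpG
   correlation R: with member effects *b*, SEs *s* and
   V = diag(s)·R·diag(s),

   β_R = (1ᵀV⁻¹b)/(1ᵀV⁻¹1),  SE = (1ᵀV⁻¹1)^(−1/2),

   and the best window per candidate is Sidak-adjusted,
   p_adj = 1 − (1 − p)^T, over the genome-wide window universe.
3. **Overlap and instruments.** Exposure DMRs are intersected with
   survival DMRs; for each shared region, mQTLs (MAF > 0.05, P < 5×10⁻⁸)
   from a reference panel are selected by iterative per-CpG LD clumping at
   r² = 0.01 starting at the sentinel CpG (lowest exposure-EWAS P), and
   each SNP's effects across the CpGs it proxies are combined by REML
   meta-analysis under the CpG correlation into an effect on *average*
   region methylation (β_GP, se_GP).
4. **Two-sample Mendelian randomization.** Per-SNP survival log-HRs
   (β_GD, additive-dosage Cox adjusting for age and sex) are combined
   with β_GP: Wald ratio β_GD/β_GP with delta-method SE for single
   instruments; for multiple, correlated-instrument IVW — GLS through the
   origin with Ω_ij = se_GD,i·se_GD,j·ρ_ij from the signed LD matrix —
   plus correlated MR-Egger whose intercept tests directional pleiotropy.
   A sentinel-CpG-only sensitivity analysis and an asymptotic power
   calculator (Φ(√(n·r²)|log OR| − z_{1−α/2}) + Φ(−√(n·r²)|log OR| −
   z_{1−α/2})) complete the stage.

The synthetic generator plants all of this with known truth: an EPIC-like
(down-scaled) CpG panel with clustered exposure-associated regions,
cis-mQTL architecture with first-order LD decay, questionnaire-derived
exposures (ever/never smoking with the cigar = 4 cigarettes rule, weekly
alcohol units, HPV16 E6 MFI dichotomised at ≥ 1000), ~26% deaths by
administrative censoring at day 1005, latent batch structure for SVA to
recover, and a mediated effect of average region methylation on the log
hazard.

## Worked example

The numbered drivers under `analysis/` run the whole study and write
their tables under `results/`:

```sh
Rscript analysis/01_simulate.R      # synthetic cohort + reference panel
Rscript analysis/02_pipeline.R      # EWAS -> DMR -> overlap -> instruments -> MR
Rscript analysis/03_calibration.R   # type-I error of every engine
Rscript analysis/04_recovery.R      # recovery of the planted effects
Rscript analysis/05_power.R         # minimum-power curves
```

`analysis/02_pipeline.R` (seed 11) prints:

```
surrogate variables: K = 3 (planted batches: 4)
EWAS smoking      top CpG cg00000002  estimate -0.0549  P 4.30e-19
EWAS survival_m1  top CpG cg00000003  estimate +6.7964  P 9.78e-06
significant DMRs (Sidak < 0.05): smoking=3, alcohol=1, hpv=0, survival_m1=1, survival_m2=1
shared exposure/survival regions: 1 (3 shared CpGs)
instrument SNPs after filtering and clumping: 3
```

The planted smoking region (a −0.05 beta shift, i.e. −5 percentage
points, in ever smokers) is found by the smoking EWAS and the DMR stage,
overlaps the survival DMR, and proceeds to MR. With only three instrument
SNPs and 409 cases the per-unit-beta hazard ratio is estimated with very
wide confidence intervals — exactly what the power curves
(`analysis/05_power.R`) predict for small variance explained — so the
precision claims of the package rest on the replicated experiments:

```
      engine n_tests rejection_rate          quantity     value truth n_rep
 linear_ewas    5000         0.0484    mr_median_loghr 0.2990637  0.30   200
    cox_ewas    1000         0.0430   mr_ci95_coverage 0.9450000  0.95   200
    snp_gwas    1000         0.0590  dmr_recovery_rate 1.0000000    NA   100
      mr_ivw     200         0.0300
```

Every engine rejects at ~5% under planted nulls; across 200 replicate
two-sample MR pipelines (panel n = 2000, cohort n = 1000) the median IVW
estimate of a planted mediated log-HR of 0.3 per unit average region
methylation is 0.299 with 94.5% CI coverage, and a 0.05-beta region shift
is recovered as a Sidak-significant DMR in 100/100 cohorts of 409.

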