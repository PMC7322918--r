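---
title: "Methylation mediation of cancer-survival risk factors: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation mediation of cancer-survival risk factors: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ewasmr)
```

`ewasmr` asks whether blood DNA methylation mediates the effect of
oropharyngeal-cancer prognostic factors (smoking, alcohol, HPV16 E6
serostatus) on roughly three-year survival, and answers it with a chain
of five analyses: single-site EWAS, differentially methylated region
(DMR) calling, exposure/survival DMR overlap, mQTL instrument
construction, and two-sample Mendelian randomization (MR) against
survival. Because the individual-level data such a study needs are
access-controlled in practice, the package is built around a
synthetic-cohort generator with known ground truth: every statistical
guarantee stated here is one the test suite or the analysis drivers
actually compute.

## The synthetic study

**Exposures.** Participants carry questionnaire records. Ever smokers
are those who smoked at least one tobacco-product equivalent per day for
at least a year, or at least 100 cigarettes in their lifetime; a cigar
counts as four cigarettes, hand-rolled and smokeless products
one-for-one. The daily-use phrase could also be read multiplicatively
(pack-year-like); we read it as a joint condition and isolate it in one
predicate (`derive_smoking_status`) so the alternative is a one-line
swap. Weekly alcohol units are the sum over wine, spirits and beer, zero
defining a non-drinker. HPV16 E6 serostatus dichotomises median
fluorescence intensity at an inclusive 1000 MFI. Default prevalences
(73% ever smokers, ~74% drinkers with a median of 22.5 units/week among
drinkers, ~67% seropositive) and the survival layout (administrative
censoring at day 1005, ~26% deaths, death from any cause as the failure
variable) mirror the clinical setting the pipeline targets; cohort size
defaults to 409.

**Methylation.** Beta values are generated as a logistic-bounded sum: a
per-CpG baseline (region members share a baseline drawn from
\[0.35, 0.65\], background CpGs from \[0.15, 0.85\]), centered per-SNP
cis effects, a latent batch shift, exposure shifts at planted regions,
and Gaussian noise on the logit scale (`noise_sd_logit = 0.2`, about
0.05 beta at mid-range CpGs). Effects are configured on the beta scale
and converted to logit coefficients by the derivative `1/(i(1-i))` at
the baseline `i`, so a configured shift reproduces itself locally while
means never leave (0, 1); a configured shift that could not be realised
(baseline plus shift outside the open interval) fails at validation
naming the region. Because the hazard acts on the *realized* average
methylation, any attenuation from the logistic link affects the panel
mQTL slopes and the cohort effects identically and cancels from the MR
ratio — the planted mediated log-HR remains the estimand.

**Genetics.** All SNPs in a region share one allele frequency (drawn
from `maf_range`, default 0.2–0.45) and haplotypes follow a Markov copy
chain: adjacent alleles agree with probability `ld_decay`, giving signed
dosage correlation exactly `ld_decay^|i-j|` in expectation. The shared
frequency is what makes that identity exact; heterogeneous per-SNP
frequencies would distort the copy-chain correlation. Each SNP carries
one signed per-allele effect applied equally to every member CpG, so a
SNP's true effect on *average* region methylation equals its per-CpG
effect — the quantity the REML meta-analysis step should recover.

**Defaults as study conditions.** The default `cis_effect` (0.015 beta
per allele) keeps each region's shared genetic variance below the
surrogate-variable detection edge at the default 2000-CpG panel — large
enough for genome-wide-significant mQTLs in a 2000-sample panel, small
enough that an SV does not align with the region average and absorb the
survival signal. The default mediated effect (log-HR 15 per unit average
beta on region 1, i.e. hazard ratio about 1.16 per percentage point of
methylation) is on the scale at which survival EWAS signals are
detectable at n = 409 with ~26% deaths. These were chosen once, at
design time, from power arithmetic — not tuned against test outcomes.

## Surrogate variables

The SVA variant is deliberately the deterministic two-step form: regress
every CpG on the model covariates, take the residual matrix, choose K by
permutation parallel analysis (each residual column permuted
independently, observed singular values compared with the 95th
percentile of the permuted ones, stopping at the first failure), and
return the first K left singular vectors — orthonormal by construction.
Given a seed it is exactly reproducible and testable against a PCA
oracle, which the iteratively reweighted variant is not. The pipeline
protects the variables of interest by including the exposures in the SV
model, standard practice so the SVs span only residual structure. The
survival outcome cannot be protected this way (a Cox outcome is not a
covariate), a limitation shared with the field's tooling: a latent
component aligned with a survival-associated region would shrink the
survival EWAS signal there.

## DMR calling

Candidates are maximal runs of CpGs with nominal P < `p_enter` (0.05),
common effect sign, and inter-CpG gaps at most `max_gap` (500 bp) — the
published defaults of regional methylation scans, made explicit
configuration. Every contiguous sub-window of length ≥ 2 is scored by
GLS under the CpG correlation estimated from covariate-residualised
methylation (the same covariates as the EWAS, so the correlation matches
the error covariance the combined SE needs), and the best window per
candidate is kept.

The multiple-testing universe is the one genuinely open design choice.
Adjusting only over the windows actually *evaluated* is anti-
conservative: candidates are selected for uniformly small member
P-values, so their best-window P is conditionally small while the count
of evaluated windows stays tiny — under a planted null this mislabels
essentially every chance candidate significant. We therefore Sidak-
adjust over all *gap-eligible* windows genome-wide (every contiguous run
of ≥ 2 CpGs whose gaps are all ≤ `max_gap`, regardless of P or sign),
the family the scan implicitly searches. The null family-wise error this
yields is measured by the property tests; overlapping windows make the
independence assumption of Sidak conservative.

Coordinates are 1-based inclusive internally; BED export converts to
0-based half-open.

## Instruments

For each shared (exposure ∩ survival) region, mQTL records are filtered
to MAF strictly above 0.05 and P strictly below 5×10⁻⁸, then selected
iteratively: CpGs are walked in ascending exposure-EWAS P starting at
the sentinel (ties broken by position, then lexicographically — the
source convention is unstated, so the tie-break is explicit and
deterministic); at each step the mQTLs of the current CpG not already
associated (present at the genome-wide filter) with an earlier CpG are
greedily clumped at r² = 0.01 within the step, and appended.
Cross-step correlation is permitted — clumps from different CpGs may
correlate — and is handled downstream by the correlation-adjusted MR
estimators, mirroring a per-CpG clumping, globally-adjusted design.
Row-order invariance of the whole selection is asserted in the tests.

Each selected SNP's effects on the region CpGs it proxies are combined
by REML: `y = 1μ + ε`, `ε ~ N(0, V + τ²I)` with `V = diag(se)·R·diag(se)`.
τ² is a scalar (one mQTL yields few CpG effects; richer heterogeneity
structure would be unidentifiable) estimated by one-dimensional bounded
optimisation of the restricted log-likelihood (tolerance 1e-8, boundary
at zero checked explicitly); μ is the GLS mean under the fitted
covariance and is the SNP's effect on average region methylation. The
implementation is checked against a τ²-grid-search oracle and against an
independently implemented mixed-model meta-analysis.

The LD matrix is computed signed and allele-aligned from the reference
panel's dosages: public LD services report unsigned r², but the
correlated-instrument estimators need the sign.

## Mendelian randomization

Single instrument: Wald ratio `β_GD/β_GP` with the two-term delta-method
SE `sqrt(se_GD²/β_GP² + β_GD²·se_GP²/β_GP⁴)` (the first-order form is
used where IVW-weight consistency requires it). Multiple instruments:
the phrase "correlation included as a covariate" admits several
readings; we implement the defensible one — GLS of the outcome effects
on the exposure effects through the origin with error covariance
`Ω = D_seGD · ρ · D_seGD` — which reduces exactly to textbook
fixed-effect IVW at ρ = I and to the Wald ratio at one SNP. MR-Egger
adds a free intercept after orienting all β_GP ≥ 0 (flipping β_GD and
the corresponding rows of ρ jointly); it needs at least three SNPs to
identify slope and intercept under correlation. Harmonisation aligns
outcome records to the instrument's effect alleles, flips swapped
alleles, drops incompatible pairs, and drops palindromic SNPs with
MAF > 0.42 (strand ambiguity is unresolvable from summary data), all
logged. CIs use the multiplier 1.959964 and P-values the standard
normal.

Power uses the asymptotic two-sided form
`Φ(√(n·r²)|log OR| − z) + Φ(−√(n·r²)|log OR| − z)`. Using the largest
single-mQTL r² makes it a deliberate lower bound on power — exact parity
with any specific online calculator is not asserted, but the formula is
cross-checked against simulation of the instrumented regression.

## Numerical choices and degenerate inputs

Correlation matrices feeding a GLS get one ridge repair (+1e-6 on the
diagonal) if not positive definite, then fail loudly. Cox fits use Efron
tie handling; non-convergent or monomorphic columns are *flagged*
(status column), never silently dropped, because the DMR stage needs
explicit missingness. Constant exposures, rank-deficient designs (named
columns), zero-event survival layers, regions absent from annotation,
and SNPs missing from the LD matrix are all hard errors naming the
offender. Interchange TSVs serialise numerics at 17 significant digits
so write→read→write is byte-identical; missing values travel as `.`;
out-of-range beta or dosage values fail at the offending line. The MAF
filter applies its strict inequality with a 1e-12 guard so that
floating-point residue (1 − 0.95 > 0.05 in doubles) cannot leak a
boundary record through.

## What the experiments do and do not show

The replicated experiments (`analysis/03_calibration.R`,
`analysis/04_recovery.R`, `scripts/acceptance.R`) use reduced problem
sizes chosen for precision per unit of compute: null calibration at 5000
CpGs (linear), 1000 CpGs (Cox), 1000 SNPs (GWAS) and 200 replicate MR
pipelines; recovery at 200 replicates of panel n = 2000 / cohort
n = 1000 with 30 cis SNPs for MR, and 100 replicates of cohort n = 409
for the DMR at a 0.05-beta shift. The generator emulates the features
the pipeline's statistics depend on — bounded beta values, spatial
clustering, LD, latent batch structure, realistic event fractions — but
not array chemistry, probe-type effects, cell-type mixtures beyond a
single batch surrogate, relatedness, trans-mQTLs, or competing risks.
Passing tests therefore certify the estimators and their calibration
under the stated generative model, not the biology of any particular
cohort. MR precision at realistic single-cohort scale is poor (the
worked example's wide intervals are the honest output); the recovery
claims are about the estimator across replicates, not about one study.
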