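#' Simulation configuration for the synthetic mQTL panel and clinical cohort
#'
#' Bundles every knob of the synthetic-data generator.  The defaults are the
#' study conditions the pipeline is exercised under: a cohort of 409
#' oropharyngeal-cancer cases with roughly 26% deaths by administrative
#' censoring at day 1005 (about 2.75 years), ~73% ever smokers, ~74% weekly
#' drinkers with a median of 22.5 units/week among drinkers, ~67% HPV16 E6
#' seropositive, an EPIC-like (down-scaled) CpG panel with spatially
#' clustered exposure-associated regions, cis-mQTL genetic architecture with
#' first-order LD decay, latent batch structure for surrogate-variable
#' analysis to recover, and a planted mediated effect of regional
#' methylation on the log hazard.
#'
#' Effect sizes are given on the methylation beta scale (difference in
#' methylation proportion).  Internally the generator works on the logit
#' scale: a configured beta-scale effect `d` at a region with baseline level
#' `i` becomes the logit coefficient `d / (i * (1 - i))`, the slope that
#' reproduces `d` locally while keeping every generated mean inside (0, 1).
#'
#' @param n_panel Reference-panel sample count (mQTL discovery sample).
#' @param n_cohort Clinical cohort sample count.
#' @param n_cpg Total CpGs simulated (region members plus background).
#' @param n_region Number of planted differentially methylated regions.
#' @param n_cpg_per_region CpGs per planted region (>= 2).
#' @param n_snp_per_region cis SNPs per region.
#' @param maf_range Bounds for the per-region minor-allele frequency,
#'   within (0, 0.5].
#' @param ld_decay Signed correlation between adjacent region SNPs; decays
#'   as `ld_decay^|i - j|` with SNP distance.
#' @param cis_effect Per-allele effect of each cis SNP on each member CpG
#'   (beta scale, magnitude; signs are drawn per SNP).  Equal across the
#'   member CpGs of a region.
#' @param exposure_effects Named list (`smoking`, `alcohol`, `hpv`) of
#'   per-region beta-scale methylation shifts.  Smoking and HPV shifts are
#'   per category (ever vs never, seropositive vs seronegative); the
#'   alcohol shift is per standard deviation of weekly units.
#' @param mediation_loghr Per-region log hazard per unit of average region
#'   methylation (the planted mediated effect).
#' @param direct_loghr Named vector of direct (non-mediated) exposure
#'   effects on the log hazard.
#' @param baseline_hazard Baseline event rate (events/day).
#' @param censor_day Administrative censoring day.
#' @param n_batch Number of latent batches (stands in for cell composition
#'   plus technical variation).
#' @param batch_effect_sd Beta-scale SD of per-batch, per-CpG shifts.
#' @param batch_affected_frac Fraction of CpGs carrying batch structure.
#' @param noise_sd_logit SD of the per-observation Gaussian noise on the
#'   logit scale (0.2 corresponds to roughly 0.05 beta at mid-range CpGs).
#' @param prev_smoking,prev_drinker,prev_hpv Exposure prevalences.
#' @param alcohol_median_units Median weekly units among drinkers.
#' @param seed Integer RNG seed; every draw in the generator derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_panel = 2000,
                       n_cohort = 409,
                       n_cpg = 2000,
                       n_region = 2,
                       n_cpg_per_region = 5,
                       n_snp_per_region = 6,
                       maf_range = c(0.2, 0.45),
                       ld_decay = 0.25,
                       cis_effect = 0.015,
                       exposure_effects = NULL,
                       mediation_loghr = NULL,
                       direct_loghr = c(smoking = 0.2, alcohol = 0, hpv = 0),
                       baseline_hazard = 3e-4,
                       censor_day = 1005,
                       n_batch = 4,
                       batch_effect_sd = 0.02,
                       batch_affected_frac = 0.3,
                       noise_sd_logit = 0.2,
                       prev_smoking = 0.73,
                       prev_drinker = 0.741,
                       prev_hpv = 0.665,
                       alcohol_median_units = 22.5,
                       seed = 1L) {
  if (is.null(exposure_effects)) {
    exposure_effects <- list(
      smoking = c(-0.05, 0.04)[seq_len(min(2, n_region))],
      alcohol = c(0, -0.02)[seq_len(min(2, n_region))],
      hpv     = c(0, 0)[seq_len(min(2, n_region))]
    )
    exposure_effects <- lapply(exposure_effects, function(x) {
      length(x) <- n_region
      x[is.na(x)] <- 0
      x
    })
  }
  if (is.null(mediation_loghr)) {
    mediation_loghr <- rep(0, n_region)
    mediation_loghr[1] <- 15
  }
  cfg <- list(
    n_panel = as.integer(n_panel), n_cohort = as.integer(n_cohort),
    n_cpg = as.integer(n_cpg), n_region = as.integer(n_region),
    n_cpg_per_region = as.integer(n_cpg_per_region),
    n_snp_per_region = as.integer(n_snp_per_region),
    maf_range = maf_range, ld_decay = ld_decay, cis_effect = cis_effect,
    exposure_effects = exposure_effects, mediation_loghr = mediation_loghr,
    direct_loghr = direct_loghr, baseline_hazard = baseline_hazard,
    censor_day = censor_day, n_batch = as.integer(n_batch),
    batch_effect_sd = batch_effect_sd,
    batch_affected_frac = batch_affected_frac,
    noise_sd_logit = noise_sd_logit,
    prev_smoking = prev_smoking, prev_drinker = prev_drinker,
    prev_hpv = prev_hpv, alcohol_median_units = alcohol_median_units,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_panel", "n_cohort", "n_cpg", "n_region",
              "n_cpg_per_region", "n_snp_per_region", "n_batch")
  for (f in counts)
    if (cfg[[f]] < 1L) stop(sprintf("`%s` must be >= 1", f))
  if (cfg$n_cpg_per_region < 2L)
    stop("`n_cpg_per_region` must be >= 2 (a region needs > 1 CpG)")
  if (cfg$n_cpg < cfg$n_region * cfg$n_cpg_per_region)
    stop("`n_cpg` smaller than the planted region CpGs")
  mr <- cfg$maf_range
  if (length(mr) != 2 || mr[1] <= 0 || mr[2] > 0.5 || mr[1] > mr[2])
    stop("`maf_range` must lie within (0, 0.5]")
  if (cfg$ld_decay < 0 || cfg$ld_decay > 1)
    stop("`ld_decay` must lie in [0, 1]")
  if (cfg$censor_day <= 0) stop("`censor_day` must be > 0")
  if (cfg$baseline_hazard <= 0) stop("`baseline_hazard` must be > 0")
  for (e in c("smoking", "alcohol", "hpv")) {
    v <- cfg$exposure_effects[[e]]
    if (is.null(v) || length(v) != cfg$n_region || anyNA(v))
      stop(sprintf("`exposure_effects$%s` must have one finite value per region", e))
  }
  if (length(cfg$mediation_loghr) != cfg$n_region || anyNA(cfg$mediation_loghr))
    stop("`mediation_loghr` must have one finite value per region")
  # Beta-scale effects must keep region means inside (0,1).  Region
  # intercepts are drawn from [0.35, 0.65]; the check uses the worst case.
  lo <- 0.35; hi <- 0.65
  for (r in seq_len(cfg$n_region)) {
    shifts <- c(vapply(cfg$exposure_effects, `[`, numeric(1), r),
                cis_up = 2 * cfg$cis_effect, cis_down = -2 * cfg$cis_effect)
    bad <- (hi + shifts >= 1) | (lo + shifts <= 0)
    if (any(bad))
      stop(sprintf(
        "degenerate config: effects push mean methylation outside (0,1) in region %d (%s)",
        r, paste(names(which(bad)), collapse = ", ")))
  }
  invisible(cfg)
}
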