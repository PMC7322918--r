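# Calibration and recovery experiments: the package's statistical
# guarantees, computed from scratch on synthetic studies.  These back the
# acceptance checks and the analysis drivers.

# Derive a disjoint seed stream per (master seed, experiment, replicate)
# so different master seeds never share replicate draws.
sub_seed <- function(seed, stream, r = 0L) {
  as.integer((as.numeric(seed) * 1000 + stream * 7 + r) %% 2147483647)
}

#' Null-calibration experiments for the association engines
#'
#' Each experiment simulates data with no association and reports the
#' fraction of tests rejected at nominal 0.05 — the per-test type-I
#' error, which should sit near 0.05.
#'
#' @param seed Integer seed.
#' @param n Samples per dataset.
#' @param n_cpg,n_snp Number of unit-level replicates (CpGs/SNPs tested).
#' @return A list with the rejection rate and the problem size.
#' @export
experiment_null_linear_ewas <- function(seed, n = 409, n_cpg = 5000) {
  M <- with_seed(sub_seed(seed, 11L), {
    beta <- matrix(stats::plogis(stats::rnorm(n * n_cpg, 0, 0.3)), n, n_cpg)
    colnames(beta) <- sprintf("cg%06d", seq_len(n_cpg))
    rownames(beta) <- sprintf("s%04d", seq_len(n))
    methylation_matrix(beta, data.frame(cpg = colnames(beta), chrom = "chr1",
                                        pos = seq_len(n_cpg) * 1000L))
  })
  x <- with_seed(sub_seed(seed, 12L), stats::rbinom(n, 1, 0.5))
  res <- run_linear_ewas(M, x)
  list(rejection_rate = mean(res$p < 0.05), n = n_cpg,
       ks = unname(suppressWarnings(stats::ks.test(res$p, "punif"))$statistic))
}

#' @rdname experiment_null_linear_ewas
#' @export
experiment_null_cox_ewas <- function(seed, n = 409, n_cpg = 1000) {
  dat <- with_seed(sub_seed(seed, 21L), {
    beta <- matrix(stats::plogis(stats::rnorm(n * n_cpg, 0, 0.3)), n, n_cpg)
    colnames(beta) <- sprintf("cg%06d", seq_len(n_cpg))
    rownames(beta) <- sprintf("s%04d", seq_len(n))
    tt <- stats::rexp(n, 3e-4)
    list(beta = beta, time = pmin(tt, 1005),
         event = as.integer(tt <= 1005))
  })
  M <- methylation_matrix(dat$beta,
                          data.frame(cpg = colnames(dat$beta), chrom = "chr1",
                                     pos = seq_len(n_cpg) * 1000L))
  res <- run_cox_ewas(M, dat$time, dat$event)
  list(rejection_rate = mean(res$p < 0.05, na.rm = TRUE), n = n_cpg)
}

#' @rdname experiment_null_linear_ewas
#' @export
experiment_null_snp_gwas <- function(seed, n = 409, n_snp = 1000) {
  dat <- with_seed(sub_seed(seed, 31L), {
    maf <- stats::runif(n_snp, 0.1, 0.5)
    d <- vapply(maf, function(p) stats::rbinom(n, 2, p), numeric(n))
    colnames(d) <- sprintf("rs%06d", seq_len(n_snp))
    tt <- stats::rexp(n, 3e-4)
    list(d = d, time = pmin(tt, 1005), event = as.integer(tt <= 1005),
         age = stats::rnorm(n, 60, 8), sex = stats::rbinom(n, 1, 0.27))
  })
  res <- run_snp_survival_gwas(dat$d, dat$time, dat$event, dat$age, dat$sex)
  list(rejection_rate = mean(res$p < 0.05, na.rm = TRUE), n = n_snp)
}

# Shared-region object for a planted region, built from the truth table
# (used when the experiment targets the MR machinery directly).
region_from_truth <- function(truth, r = 1L) {
  cpgs <- strsplit(truth$regions$cpgs[r], ",", fixed = TRUE)[[1]]
  structure(list(exposure = "truth", chrom = truth$regions$chrom[r],
                 start = truth$regions$start[r],
                 end = truth$regions$end[r],
                 shared_cpgs = cpgs, sentinel = cpgs[1]),
            class = "shared_region")
}

# One two-sample MR pass over a simulated panel + cohort: panel mQTLs and
# LD, instrument construction on the planted region, per-SNP survival
# GWAS in the cohort, correlated IVW.
mr_once <- function(cfg) {
  panel <- simulate_reference_panel(cfg)
  cohort <- simulate_clinical_cohort(cfg, panel$truth)
  mq <- panel_mqtls(panel)
  ld <- panel_ld(panel)
  reg <- region_from_truth(panel$truth, 1L)
  # CpG ordering proxy for instrument iteration: position order
  ord <- data.frame(cpg = reg$shared_cpgs, chrom = reg$chrom,
                    pos = seq_along(reg$shared_cpgs),
                    p = seq_along(reg$shared_cpgs) * 1e-6,
                    estimate = 0.02, se = 0.005, n = cfg$n_cohort,
                    status = "ok", stringsAsFactors = FALSE)
  cc <- residual_cor(panel$methylation, reg$shared_cpgs)
  inst <- build_instrument_set(reg, mq, ld, ord, cc)
  if (nrow(inst$snps) == 0) return(NULL)
  gw <- run_snp_survival_gwas(
    cohort$dosage[, inst$snps$snp, drop = FALSE], cohort$survival_days,
    cohort$event, cohort$phenotypes$age, cohort$phenotypes$sex)
  mr <- mr_region(inst, gw, ld)
  mr[mr$analysis == "all_dmr_cpgs" & mr$method == "ivw", , drop = FALSE]
}

#' End-to-end MR calibration and recovery experiments
#'
#' `experiment_mr_null` runs replicate two-sample MR pipelines (panel
#' mQTLs -> instruments -> cohort survival GWAS -> correlated IVW) with
#' the mediated effect set to zero and reports the fraction of IVW
#' P-values below 0.05.  `experiment_mr_recovery` plants a mediated log
#' hazard of `truth` per unit average region methylation and reports the
#' median IVW estimate and the empirical 95% CI coverage across
#' replicates.
#'
#' @param seed Integer seed; each replicate draws from its own derived
#'   stream.
#' @param n_rep Number of replicate pipelines.
#' @param truth Planted mediated log-HR per unit average beta.
#' @return A list of summary quantities plus the replicate table.
#' @export
experiment_mr_null <- function(seed, n_rep = 200) {
  p <- vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_panel = 800, n_cohort = 400, n_cpg = 3,
                      n_region = 1, n_cpg_per_region = 3,
                      n_snp_per_region = 8, maf_range = c(0.25, 0.45),
                      ld_decay = 0.1, cis_effect = 0.08,
                      exposure_effects = list(smoking = 0, alcohol = 0,
                                              hpv = 0),
                      mediation_loghr = 0,
                      direct_loghr = c(smoking = 0, alcohol = 0, hpv = 0),
                      seed = sub_seed(seed, 41L, r))
    out <- mr_once(cfg)
    if (is.null(out)) NA_real_ else out$p
  }, numeric(1))
  list(rejection_rate = mean(p < 0.05, na.rm = TRUE), n = n_rep,
       p_values = p)
}

#' @rdname experiment_mr_null
#' @export
experiment_mr_recovery <- function(seed, n_rep = 200, truth = 0.3) {
  rows <- lapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_panel = 2000, n_cohort = 1000, n_cpg = 3,
                      n_region = 1, n_cpg_per_region = 3,
                      n_snp_per_region = 30, maf_range = c(0.25, 0.45),
                      ld_decay = 0.05, cis_effect = 0.12,
                      exposure_effects = list(smoking = 0, alcohol = 0,
                                              hpv = 0),
                      mediation_loghr = truth,
                      direct_loghr = c(smoking = 0, alcohol = 0, hpv = 0),
                      seed = sub_seed(seed, 51L, r))
    mr_once(cfg)
  })
  tab <- do.call(rbind, rows)
  cover <- tab$beta - 1.959964 * tab$se <= truth &
    truth <= tab$beta + 1.959964 * tab$se
  list(median_beta = stats::median(tab$beta), coverage = mean(cover),
       truth = truth, n = nrow(tab), estimates = tab)
}

#' Planted-DMR recovery experiment
#'
#' Replicate cohorts of `n` samples carry one region whose methylation is
#' shifted by `shift` (beta scale) in ever smokers; each replicate runs
#' the exposure EWAS and the DMR caller and scores recovery as a
#' Sidak-significant DMR overlapping the planted interval.
#'
#' @param seed Integer seed.
#' @param n_rep Replicates.
#' @param shift Planted beta-scale shift.
#' @param n Cohort size.
#' @return List with the recovery rate and the problem size.
#' @export
experiment_dmr_recovery <- function(seed, n_rep = 100, shift = 0.05,
                                    n = 409) {
  hit <- vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_panel = 10, n_cohort = n, n_cpg = 300,
                      n_region = 1, n_cpg_per_region = 5,
                      n_snp_per_region = 2, cis_effect = 0.01,
                      exposure_effects = list(smoking = shift, alcohol = 0,
                                              hpv = 0),
                      mediation_loghr = 0,
                      direct_loghr = c(smoking = 0, alcohol = 0, hpv = 0),
                      seed = sub_seed(seed, 61L, r))
    panel <- simulate_reference_panel(cfg)
    cohort <- simulate_clinical_cohort(cfg, panel$truth)
    ew <- run_linear_ewas(cohort$methylation, cohort$phenotypes$smoking)
    d <- call_dmrs(ew, cohort$methylation)
    tr <- panel$truth$regions
    any(d$significant & d$chrom == tr$chrom[1] &
          d$start <= tr$end[1] & d$end >= tr$start[1])
  }, logical(1))
  list(recovery_rate = mean(hit), n = n_rep)
}
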