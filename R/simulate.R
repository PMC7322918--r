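# Synthetic mQTL reference panel and clinical cohort with known
# genotype -> methylation -> survival mediation.
#
# The genetic architecture (CpG layout, SNP frequencies, cis effects,
# batch structure) is drawn once from the config seed and shared between
# the panel and the cohort; sample-level draws use offset seeds so the two
# samples are independent draws from the same population.

# ---- architecture ---------------------------------------------------------

sim_architecture <- function(cfg) {
  with_seed(cfg$seed, {
    n_member <- cfg$n_region * cfg$n_cpg_per_region
    n_bg <- cfg$n_cpg - n_member

    cpg_id <- sprintf("cg%08d", seq_len(cfg$n_cpg))
    region_id <- rep(NA_integer_, cfg$n_cpg)
    chrom <- character(cfg$n_cpg)
    pos <- integer(cfg$n_cpg)

    # Planted regions: one per chromosome, members ~60-140 bp apart.
    idx <- 1L
    region_rows <- vector("list", cfg$n_region)
    for (r in seq_len(cfg$n_region)) {
      k <- cfg$n_cpg_per_region
      ii <- idx:(idx + k - 1L)
      gaps <- sample(60:140, k - 1L, replace = TRUE)
      p0 <- 1e6 + sample.int(1e5, 1L)
      pp <- as.integer(p0 + c(0L, cumsum(gaps)))
      chrom[ii] <- sprintf("chr%d", ((r - 1L) %% 22L) + 1L)
      pos[ii] <- pp
      region_id[ii] <- r
      region_rows[[r]] <- data.frame(
        region = r, chrom = chrom[ii][1], start = pp[1], end = pp[k],
        n_cpg = k, stringsAsFactors = FALSE)
      idx <- idx + k
    }

    # Background CpGs: round-robin over chromosomes, gaps log-uniform in
    # 50 bp - 20 kb so that a realistic fraction of neighbours fall within
    # DMR-calling distance of each other.
    if (n_bg > 0) {
      ii <- idx:(idx + n_bg - 1L)
      bchrom <- sprintf("chr%d", ((seq_len(n_bg) - 1L) %% 22L) + 1L)
      gaps <- as.integer(round(10^stats::runif(n_bg, 1.7, 4.3)))
      bpos <- integer(n_bg)
      for (ch in unique(bchrom)) {
        sel <- which(bchrom == ch)
        bpos[sel] <- as.integer(1e7 + cumsum(gaps[sel]))
      }
      chrom[ii] <- bchrom
      pos[ii] <- bpos
    }

    anno <- data.frame(cpg = cpg_id, chrom = chrom, pos = pos,
                       region = region_id, stringsAsFactors = FALSE)
    anno <- anno[order(anno$chrom, anno$pos), , drop = FALSE]
    rownames(anno) <- NULL

    intercept <- numeric(cfg$n_cpg)
    names(intercept) <- anno$cpg
    is_member <- !is.na(anno$region)
    region_intercept <- stats::runif(cfg$n_region, 0.35, 0.65)
    intercept[is_member] <- region_intercept[anno$region[is_member]]
    intercept[!is_member] <- stats::runif(sum(!is_member), 0.15, 0.85)

    # SNP layer: per region, one shared MAF and a chain of cis SNPs.
    snp_rows <- vector("list", cfg$n_region)
    ctr <- 0L
    for (r in seq_len(cfg$n_region)) {
      m <- cfg$n_snp_per_region
      maf <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      snp_rows[[r]] <- data.frame(
        snp = sprintf("rs%06d", ctr + seq_len(m)), region = r,
        chrom = region_rows[[r]]$chrom,
        pos = as.integer(region_rows[[r]]$start - 5e4 + seq_len(m) * 500L),
        maf = maf, stringsAsFactors = FALSE)
      ctr <- ctr + m
    }
    snps <- do.call(rbind, snp_rows)

    # cis effects: one signed per-allele effect per SNP, equal across the
    # region's member CpGs.
    snps$effect <- sample(c(-1, 1), nrow(snps), replace = TRUE) * cfg$cis_effect
    cis <- do.call(rbind, lapply(seq_len(nrow(snps)), function(i) {
      r <- snps$region[i]
      data.frame(snp = snps$snp[i], region = r,
                 cpg = anno$cpg[!is.na(anno$region) & anno$region == r],
                 effect = snps$effect[i], stringsAsFactors = FALSE)
    }))
    rownames(cis) <- NULL

    # Latent batch structure: shifts for a fixed subset of CpGs.
    affected <- sort(sample.int(cfg$n_cpg, round(cfg$batch_affected_frac * cfg$n_cpg)))
    batch_shift <- matrix(0, cfg$n_batch, cfg$n_cpg,
                          dimnames = list(NULL, anno$cpg))
    batch_shift[, affected] <- stats::rnorm(cfg$n_batch * length(affected),
                                            0, cfg$batch_effect_sd)

    regions <- do.call(rbind, region_rows)
    regions$intercept <- region_intercept
    regions$eff_smoking <- cfg$exposure_effects$smoking
    regions$eff_alcohol <- cfg$exposure_effects$alcohol
    regions$eff_hpv <- cfg$exposure_effects$hpv
    regions$mediation_loghr <- cfg$mediation_loghr
    regions$cpgs <- vapply(seq_len(cfg$n_region), function(r)
      paste(anno$cpg[!is.na(anno$region) & anno$region == r], collapse = ","),
      character(1))

    truth <- structure(
      list(regions = regions, cis = cis,
           snps = snps[, c("snp", "region", "chrom", "pos", "maf")]),
      class = "truth_table")

    list(anno = anno, intercept = intercept, snps = snps, cis = cis,
         batch_shift = batch_shift, truth = truth)
  })
}

# ---- shared draw machinery ------------------------------------------------

# Haplotype copy-chain: adjacent alleles share value with probability
# `ld_decay`, giving corr(adjacent dosages) = ld_decay exactly when all
# SNPs in the region share one allele frequency.
draw_region_haplotypes <- function(n_hap, m, p, ld) {
  h <- matrix(0L, n_hap, m)
  h[, 1] <- stats::rbinom(n_hap, 1L, p)
  if (m > 1) for (j in 2:m) {
    copy <- stats::rbinom(n_hap, 1L, ld)
    h[, j] <- ifelse(copy == 1L, h[, j - 1L], stats::rbinom(n_hap, 1L, p))
  }
  h
}

draw_dosage <- function(arch, n) {
  snps <- arch$snps
  out <- matrix(0, n, nrow(snps), dimnames = list(NULL, snps$snp))
  for (r in unique(snps$region)) {
    sel <- which(snps$region == r)
    p <- snps$maf[sel][1]
    h1 <- draw_region_haplotypes(n, length(sel), p, attr(arch, "ld_decay"))
    h2 <- draw_region_haplotypes(n, length(sel), p, attr(arch, "ld_decay"))
    out[, sel] <- h1 + h2
  }
  out
}

# Build the beta matrix from the architecture plus per-sample logit shifts.
# Configured beta-scale effects are converted to logit coefficients by the
# derivative 1 / (i (1 - i)) at each CpG's baseline level i.
build_beta <- function(arch, cfg, dosage, batch, extra_logit = NULL) {
  n <- nrow(dosage)
  anno <- arch$anno
  i0 <- arch$intercept[anno$cpg]
  deriv <- i0 * (1 - i0)

  l <- matrix(stats::qlogis(i0), n, nrow(anno), byrow = TRUE,
              dimnames = list(NULL, anno$cpg))

  # cis genetic contribution, centered so the population mean stays at i0
  if (nrow(arch$cis) > 0) {
    B <- matrix(0, ncol(dosage), nrow(anno),
                dimnames = list(colnames(dosage), anno$cpg))
    B[cbind(arch$cis$snp, arch$cis$cpg)] <- arch$cis$effect
    B <- sweep(B, 2, deriv, "/")
    p2 <- 2 * arch$snps$maf[match(colnames(dosage), arch$snps$snp)]
    dc <- sweep(dosage, 2, p2, "-")
    l <- l + dc %*% B
  }

  bs <- sweep(arch$batch_shift, 2, deriv[colnames(arch$batch_shift)], "/")
  l <- l + bs[batch, , drop = FALSE]

  if (!is.null(extra_logit)) l <- l + extra_logit
  l <- l + stats::rnorm(length(l), 0, cfg$noise_sd_logit)
  stats::plogis(l)
}

# ---- public simulators ----------------------------------------------------

#' Simulate the mQTL reference panel
#'
#' Draws genotypes under Hardy-Weinberg equilibrium with first-order LD
#' decay within each region, and methylation beta values as a
#' logistic-bounded sum of a CpG baseline, centered per-SNP cis effects,
#' a latent batch shift and Gaussian logit-scale noise.  The returned
#' truth table records every nonzero planted effect.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `panel_data` with elements `dosage` (samples x
#'   SNPs additive dosages), `methylation` (a [methylation_matrix()]),
#'   `phenotypes` (age, sex, batch) and `truth` (a `truth_table`).
#' @export
simulate_reference_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  arch <- sim_architecture(cfg)
  attr(arch, "ld_decay") <- cfg$ld_decay
  with_seed(cfg$seed + 1L, {
    n <- cfg$n_panel
    dosage <- draw_dosage(arch, n)
    batch <- sample.int(cfg$n_batch, n, replace = TRUE)
    beta <- build_beta(arch, cfg, dosage, batch)
    sample_ids <- sprintf("panel_%04d", seq_len(n))
    rownames(dosage) <- sample_ids
    rownames(beta) <- sample_ids
    phen <- data.frame(
      sample_id = sample_ids,
      age = round(stats::rnorm(n, 50, 12), 1),
      sex = stats::rbinom(n, 1L, 0.5),
      batch = batch, stringsAsFactors = FALSE)
    structure(
      list(dosage = dosage,
           methylation = methylation_matrix(beta, arch$anno[, c("cpg", "chrom", "pos", "region")]),
           phenotypes = phen, truth = arch$truth),
      class = "panel_data")
  })
}

#' Simulate the clinical cohort with planted mediation
#'
#' Uses the same genetic architecture as the paired reference panel.
#' Exposures (derived from simulated questionnaires by the study's rules)
#' shift methylation at the planted regions; the per-sample log hazard is
#' the sum over regions of `mediation_loghr` times the realized average
#' region methylation, plus any configured direct exposure effects.
#' Survival times are exponential with that hazard and administratively
#' censored at `censor_day`.
#'
#' @param cfg A [sim_config()]; must be the config used for the panel.
#' @param panel_truth The `truth_table` returned by
#'   [simulate_reference_panel()]; verified against the config.
#' @return A list of class `cohort_data` with `dosage`, `methylation`,
#'   `phenotypes` (derived exposures + age + sex + batch),
#'   `survival_days`, `event`, and the `questionnaires` the exposures were
#'   derived from.  The realized event fraction is attached as attribute
#'   `event_fraction`.
#' @export
simulate_clinical_cohort <- function(cfg, panel_truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(panel_truth, "truth_table"))
  arch <- sim_architecture(cfg)
  attr(arch, "ld_decay") <- cfg$ld_decay
  if (!isTRUE(all.equal(arch$truth, panel_truth)))
    stop("`panel_truth` does not match the architecture implied by `cfg`")

  with_seed(cfg$seed + 2L, {
    n <- cfg$n_cohort
    dosage <- draw_dosage(arch, n)
    batch <- sample.int(cfg$n_batch, n, replace = TRUE)
    q <- sim_questionnaires(cfg, n)

    smoking <- as.integer(derive_smoking_status(q))
    alcohol_units <- derive_alcohol_units(q)
    hpv <- as.integer(classify_hpv_serostatus(q$hpv16_e6_mfi))
    alc_sd <- stats::sd(alcohol_units)
    alc_z <- if (alc_sd > 0) (alcohol_units - mean(alcohol_units)) / alc_sd
             else alcohol_units * 0

    # exposure shifts on the logit scale at the member CpGs
    anno <- arch$anno
    extra <- matrix(0, n, nrow(anno), dimnames = list(NULL, anno$cpg))
    tr <- arch$truth$regions
    for (r in seq_len(nrow(tr))) {
      member <- strsplit(tr$cpgs[r], ",", fixed = TRUE)[[1]]
      i0 <- tr$intercept[r]
      shift <- (tr$eff_smoking[r] * smoking +
                tr$eff_alcohol[r] * alc_z +
                tr$eff_hpv[r] * hpv) / (i0 * (1 - i0))
      extra[, member] <- extra[, member] + shift
    }

    beta <- build_beta(arch, cfg, dosage, batch, extra)
    sample_ids <- sprintf("case_%04d", seq_len(n))
    rownames(dosage) <- sample_ids
    rownames(beta) <- sample_ids

    # hazard: mediated regional methylation + direct exposure effects,
    # centered so baseline_hazard sets the marginal event rate
    eta <- numeric(n)
    for (r in seq_len(nrow(tr))) {
      member <- strsplit(tr$cpgs[r], ",", fixed = TRUE)[[1]]
      avg <- rowMeans(beta[, member, drop = FALSE])
      eta <- eta + tr$mediation_loghr[r] * (avg - mean(avg))
    }
    dl <- cfg$direct_loghr
    expo <- cbind(smoking = smoking, alcohol = alc_z, hpv = hpv)
    for (e in names(dl)) if (dl[[e]] != 0)
      eta <- eta + dl[[e]] * (expo[, e] - mean(expo[, e]))

    tt <- stats::rexp(n, rate = cfg$baseline_hazard * exp(eta))
    event <- as.integer(tt <= cfg$censor_day)
    survival_days <- pmin(tt, cfg$censor_day)
    ef <- mean(event)
    if (ef == 0 || ef == 1)
      stop(sprintf("degenerate survival layer: event fraction is %d", as.integer(ef)))

    phen <- data.frame(
      sample_id = sample_ids, smoking = smoking,
      alcohol_units = alcohol_units, hpv = hpv,
      age = round(stats::rnorm(n, 60, 8), 1),
      sex = stats::rbinom(n, 1L, 0.27),
      batch = batch, stringsAsFactors = FALSE)

    structure(
      list(dosage = dosage,
           methylation = methylation_matrix(beta, anno[, c("cpg", "chrom", "pos", "region")]),
           phenotypes = phen, survival_days = survival_days, event = event,
           questionnaires = q),
      class = "cohort_data", event_fraction = ef)
  })
}

# Simulated questionnaires matching the exposure-derivation rules: ever
# smokers report daily cigarettes over years; drinkers report weekly units
# log-normal around the target median; HPV16 E6 MFI is bimodal around the
# 1000-MFI cutoff.
sim_questionnaires <- function(cfg, n) {
  ever <- stats::rbinom(n, 1L, cfg$prev_smoking) == 1L
  drinker <- stats::rbinom(n, 1L, cfg$prev_drinker) == 1L
  seropos <- stats::rbinom(n, 1L, cfg$prev_hpv) == 1L

  cig <- ifelse(ever, sample(5:40, n, replace = TRUE), 0)
  yrs <- ifelse(ever, sample(2:45, n, replace = TRUE), 0)
  life <- ifelse(ever, round(cig * yrs * 365), 0)

  total_units <- ifelse(
    drinker,
    stats::rlnorm(n, log(cfg$alcohol_median_units), 0.6), 0)
  w <- matrix(stats::rgamma(3 * n, 1), n, 3)
  w <- w / rowSums(w)

  mfi <- ifelse(seropos,
                1000 + stats::rexp(n, 1 / 2000),
                stats::runif(n, 0, 999))

  questionnaire(
    cigarettes_per_day = cig, handrolled_per_day = 0, cigars_per_day = 0,
    smokeless_per_day = 0, years_smoked = yrs, lifetime_cigarettes = life,
    wine_units = total_units * w[, 1], spirit_units = total_units * w[, 2],
    beer_units = total_units * w[, 3], hpv16_e6_mfi = mfi)
}
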