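# Two-sample Mendelian randomization of region-average methylation on
# survival: Wald ratio with delta-method SEs, correlated-instrument IVW
# and MR-Egger by generalised least squares, harmonisation, and an
# asymptotic power calculator.

CI_Z <- 1.959964

mr_estimate_row <- function(method, n_snp, beta, se,
                            intercept = NA_real_, intercept_se = NA_real_) {
  out <- data.frame(
    method = method, n_snp = as.integer(n_snp), beta = beta, se = se,
    hr = exp(beta), ci_low = exp(beta - CI_Z * se),
    ci_high = exp(beta + CI_Z * se), p = z_pvalue(beta, se),
    intercept = intercept, intercept_se = intercept_se,
    intercept_ci_low = intercept - CI_Z * intercept_se,
    intercept_ci_high = intercept + CI_Z * intercept_se,
    intercept_p = if (is.na(intercept)) NA_real_
                  else z_pvalue(intercept, intercept_se),
    stringsAsFactors = FALSE)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Wald ratio causal estimate for a single instrument
#'
#' `beta = bGD / bGP` — the SNP-outcome log hazard divided by the
#' SNP-exposure effect — with the delta-method SE.  The default
#' second-order form is
#' `se = sqrt(seGD^2/bGP^2 + bGD^2 seGP^2 / bGP^4)`; `order = 1` drops
#' the second term (the IVW-weight convention).
#'
#' @param b_gd,se_gd SNP-outcome (survival) log-HR and SE.
#' @param b_gp,se_gp SNP-exposure (region methylation) effect and SE.
#' @param order Delta-method order, 1 or 2 (default 2).
#' @return One-row `mr_estimate` data frame (method `"wald"`).
#' @export
wald_ratio <- function(b_gd, se_gd, b_gp, se_gp, order = 2) {
  if (b_gp == 0) stop("b_gp is zero: Wald ratio undefined (weak instrument)")
  beta <- b_gd / b_gp
  v <- se_gd^2 / b_gp^2
  if (order == 2) v <- v + b_gd^2 * se_gp^2 / b_gp^4
  mr_estimate_row("wald", 1L, beta, sqrt(v))
}

# Build the GLS error covariance Omega_ij = seGD_i seGD_j rho_ij with a
# one-shot ridge repair on rho.
mr_omega_chol <- function(se_gd, rho, ridge = 1e-6) {
  tryCatch(chol_with_ridge(se_gd, rho, ridge),
           error = function(e) stop("LD matrix not PSD after ridge repair"))
}

#' Correlated-instrument IVW estimate
#'
#' Generalised weighted least squares of the SNP-outcome effects on the
#' SNP-exposure effects through the origin, with error covariance
#' `Omega_ij = seGD_i seGD_j rho_ij`:
#' `beta = (X' Omega^-1 Y) / (X' Omega^-1 X)`,
#' `se = (X' Omega^-1 X)^-1/2`.  With `rho = I` this equals textbook
#' fixed-effect IVW of the Wald ratios with first-order weights.  A
#' single SNP delegates to [wald_ratio()] with the first-order SE.
#'
#' @param b_gd,se_gd Per-SNP outcome log-HRs and SEs.
#' @param b_gp,se_gp Per-SNP exposure effects and SEs.
#' @param rho Signed SNP correlation matrix (identity if NULL).
#' @return One-row `mr_estimate` data frame (method `"ivw"`).
#' @export
ivw_correlated <- function(b_gd, se_gd, b_gp, se_gp, rho = NULL) {
  n <- length(b_gd)
  stopifnot(length(se_gd) == n, length(b_gp) == n, length(se_gp) == n)
  if (n == 1) {
    out <- wald_ratio(b_gd, se_gd, b_gp, se_gp, order = 1)
    out$method <- "ivw"
    return(out)
  }
  if (is.null(rho)) rho <- diag(n)
  ch <- mr_omega_chol(se_gd, rho)
  Oi_x <- chol_solve(ch$chol, b_gp)
  xtox <- sum(b_gp * Oi_x)
  beta <- sum(Oi_x * b_gd) / xtox
  mr_estimate_row("ivw", n, beta, xtox^(-0.5))
}

#' Correlated-instrument MR-Egger estimate
#'
#' GLS regression of the SNP-outcome effects on `[1, bGP]` under the same
#' error covariance as [ivw_correlated()], after harmonising signs so
#' every `bGP >= 0` (flipping `bGD` jointly).  The slope is the causal
#' estimate; the intercept with its CI and P is the directional-pleiotropy
#' test.  At least three SNPs are required.
#'
#' @inheritParams ivw_correlated
#' @param intercept_zero Internal check mode: pin the intercept at 0, in
#'   which case the slope equals the IVW estimate.
#' @return One-row `mr_estimate` data frame (method `"egger"`).
#' @export
egger_correlated <- function(b_gd, se_gd, b_gp, se_gp, rho = NULL,
                             intercept_zero = FALSE) {
  n <- length(b_gd)
  stopifnot(length(se_gd) == n, length(b_gp) == n, length(se_gp) == n)
  flip <- sign(b_gp)
  flip[flip == 0] <- 1
  x <- b_gp * flip
  y <- b_gd * flip
  if (intercept_zero) {
    out <- ivw_correlated(y, se_gd, x, se_gp, rho)
    out$method <- "egger"
    return(out)
  }
  if (n < 3)
    stop("MR-Egger with correlated instruments requires >= 3 SNPs")
  if (is.null(rho)) rho <- diag(n)
  if (!is.null(rho)) {
    # sign-flips propagate to the correlation of the flipped effects
    rho <- rho * tcrossprod(flip)
  }
  ch <- mr_omega_chol(se_gd, rho)
  X <- cbind(1, x)
  OiX <- apply(X, 2, function(col) chol_solve(ch$chol, col))
  XtOX <- crossprod(X, OiX)
  XtOy <- crossprod(OiX, y)
  cov <- solve(XtOX)
  coefs <- cov %*% XtOy
  mr_estimate_row("egger", n, beta = coefs[2], se = sqrt(cov[2, 2]),
                  intercept = coefs[1], intercept_se = sqrt(cov[1, 1]))
}

#' Harmonise instrument and outcome summary statistics
#'
#' Aligns the SNP-survival records to the instrument's effect alleles:
#' matching alleles pass through, swapped alleles flip the sign of the
#' outcome effect, incompatible allele pairs are dropped, and palindromic
#' SNPs (A/T or C/G) with MAF > 0.42 are dropped as strand-unresolvable.
#' Dropped SNPs are recorded in the harmonisation log.
#'
#' @param inst_snps The `snps` table of an `instrument_set`.
#' @param snp_survival A `snp_survival` table from
#'   [run_snp_survival_gwas()].
#' @return List: `data` (merged per-SNP table with `beta_gp`, `se_gp`,
#'   `loghr`, `se_gd`, flips applied), `log` (per-SNP action).
#' @export
harmonise_mr_input <- function(inst_snps, snp_survival) {
  log <- data.frame(snp = character(), action = character(),
                    stringsAsFactors = FALSE)
  keep <- list()
  pal <- function(a, b) paste0(a, b) %in% c("AT", "TA", "CG", "GC")
  for (i in seq_len(nrow(inst_snps))) {
    s <- inst_snps[i, ]
    o <- snp_survival[snp_survival$snp == s$snp, , drop = FALSE]
    act <- NULL
    if (nrow(o) == 0) act <- "missing_outcome"
    else if (o$status[1] != "ok" || is.na(o$loghr[1])) act <- "flagged_outcome"
    else if (pal(s$effect_allele, s$other_allele) &&
             min(s$eaf, 1 - s$eaf) > 0.42) act <- "palindromic_dropped"
    if (is.null(act)) {
      flip <- if (o$effect_allele[1] == s$effect_allele) 1
              else if (o$effect_allele[1] == s$other_allele) -1
              else NA
      if (is.na(flip)) act <- "incompatible_alleles"
      else {
        row <- s
        row$loghr <- o$loghr[1] * flip
        row$se_gd <- o$se[1]
        keep[[length(keep) + 1L]] <- row
        act <- if (flip == 1) "kept" else "flipped"
      }
    }
    log <- rbind(log, data.frame(snp = s$snp, action = act,
                                 stringsAsFactors = FALSE))
  }
  data <- if (length(keep)) do.call(rbind, keep) else
    inst_snps[0, , drop = FALSE]
  rownames(data) <- NULL
  list(data = data, log = log)
}

#' MR analysis of one shared region
#'
#' Harmonises the instrument against the SNP-survival summary
#' statistics, then runs the full-instrument analysis (Wald for one SNP,
#' correlated-IVW for two or more, plus correlated MR-Egger for three or
#' more) and the sentinel-CpG sensitivity analysis restricted to mQTLs of
#' the sentinel CpG (Wald for one SNP, IVW otherwise, with the sentinel
#' CpG's own mQTL effect as the exposure effect).
#'
#' @param instrument An `instrument_set` from [build_instrument_set()].
#' @param snp_survival A `snp_survival` table.
#' @param ld Signed LD matrix covering the instrument SNPs.
#' @param region_label Label written in the `region` column.
#' @return Data frame of `mr_estimate` rows with `region` and `analysis`
#'   (`all_dmr_cpgs` / `sentinel_only`) columns; the harmonisation log is
#'   attached as attribute `harmonisation`.  Attribute `skipped = TRUE`
#'   with zero rows when nothing is harmonisable.
#' @export
mr_region <- function(instrument, snp_survival, ld, region_label = NULL) {
  stopifnot(inherits(instrument, "instrument_set"))
  if (is.null(region_label)) {
    rg <- instrument$region
    region_label <- sprintf("%s:%d-%d", rg$chrom, rg$start, rg$end)
  }
  harm <- harmonise_mr_input(instrument$snps, snp_survival)
  d <- harm$data
  empty <- cbind(data.frame(region = character(), analysis = character()),
                 mr_estimate_row("ivw", 1L, 0, 1)[0, ])
  if (nrow(d) == 0)
    return(structure(empty, skipped = TRUE, harmonisation = harm$log))

  rho <- ld[d$snp, d$snp, drop = FALSE]
  rows <- list()
  if (nrow(d) == 1) {
    rows$full <- wald_ratio(d$loghr, d$se_gd, d$beta_gp, d$se_gp)
  } else {
    rows$full <- ivw_correlated(d$loghr, d$se_gd, d$beta_gp, d$se_gp, rho)
    if (nrow(d) >= 3)
      rows$egger <- egger_correlated(d$loghr, d$se_gd, d$beta_gp, d$se_gp, rho)
  }
  full <- do.call(rbind, rows)
  full <- cbind(data.frame(region = region_label, analysis = "all_dmr_cpgs",
                           stringsAsFactors = FALSE), full)

  sent <- d[!is.na(d$sentinel_beta), , drop = FALSE]
  out <- full
  if (nrow(sent) > 0) {
    srow <- if (nrow(sent) == 1)
      wald_ratio(sent$loghr, sent$se_gd, sent$sentinel_beta, sent$sentinel_se)
    else
      ivw_correlated(sent$loghr, sent$se_gd, sent$sentinel_beta,
                     sent$sentinel_se, ld[sent$snp, sent$snp, drop = FALSE])
    srow <- cbind(data.frame(region = region_label,
                             analysis = "sentinel_only",
                             stringsAsFactors = FALSE), srow)
    out <- rbind(full, srow)
  }
  rownames(out) <- NULL
  structure(out, harmonisation = harm$log)
}

#' Asymptotic power for an MR analysis of survival
#'
#' Two-sided power of the instrumented log-HR test at level `alpha`:
#' `Phi(sqrt(n r2) |log OR| - z) + Phi(-sqrt(n r2) |log OR| - z)` with
#' `z = qnorm(1 - alpha/2)`.  `r2` is the variance in the exposure
#' explained by the instrument; using the largest single-mQTL r2 makes
#' the result a conservative minimum bound on power.
#'
#' @param n Outcome sample size.
#' @param r2 Variance explained, in (0, 1].
#' @param or_grid Odds/hazard-ratio values to evaluate.
#' @param alpha Test level (default 0.05).
#' @return Data frame `or`, `power`.
#' @export
mr_power <- function(n, r2, or_grid, alpha = 0.05) {
  stopifnot(n >= 1, r2 > 0, r2 <= 1, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  ncp <- sqrt(n * r2) * abs(log(or_grid))
  data.frame(or = or_grid,
             power = stats::pnorm(ncp - z) + stats::pnorm(-ncp - z))
}
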