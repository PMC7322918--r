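# Per-CpG association engines: linear EWAS of exposures, Cox EWAS of
# survival, per-SNP survival GWAS, surrogate-variable estimation, and the
# multiple-testing thresholds.

#' Methylation matrix container
#'
#' Samples x CpGs beta values in \[0, 1\] plus a per-CpG genomic
#' annotation (chromosome, 1-based position).  Annotation rows are kept
#' sorted by chromosome and position; positions must be strictly
#' increasing within a chromosome.
#'
#' @param beta Numeric matrix, samples in rows, CpGs in columns (named).
#' @param annotation Data frame with columns `cpg`, `chrom`, `pos` (and
#'   optionally a planted-region id).
#' @return An object of class `methylation_matrix`.
#' @export
methylation_matrix <- function(beta, annotation) {
  stopifnot(is.matrix(beta), is.data.frame(annotation),
            all(c("cpg", "chrom", "pos") %in% names(annotation)))
  if (anyNA(annotation$pos) || anyNA(annotation$chrom))
    stop("annotation has missing CpG positions")
  if (any(beta < 0 | beta > 1)) stop("beta values must lie in [0, 1]")
  annotation <- annotation[order(annotation$chrom, annotation$pos), , drop = FALSE]
  rownames(annotation) <- NULL
  if (any(unlist(tapply(annotation$pos, annotation$chrom, function(p) diff(p) <= 0))))
    stop("CpG positions must be strictly increasing within a chromosome")
  if (!setequal(colnames(beta), annotation$cpg))
    stop("beta columns and annotation CpGs disagree")
  beta <- beta[, annotation$cpg, drop = FALSE]
  structure(list(beta = beta, annotation = annotation,
                 sample_ids = rownames(beta)),
            class = "methylation_matrix")
}

# Design-matrix helper: intercept + covariates + SVs, with rank check.
build_design <- function(n, covariates = NULL, svs = NULL, extra = NULL) {
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(extra)) X <- cbind(X, extra)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X <- cbind(X, covariates)
  }
  if (!is.null(svs)) {
    sv <- if (inherits(svs, "sv_set")) svs$sv else as.matrix(svs)
    if (ncol(sv) > 0) {
      colnames(sv) <- sprintf("SV%d", seq_len(ncol(sv)))
      X <- cbind(X, sv)
    }
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", ")))
  }
  X
}

#' Estimate surrogate variables by residual SVD with permutation selection
#'
#' Two-step procedure: each CpG is regressed on the model covariates; the
#' number K of surrogate variables is chosen by permutation parallel
#' analysis on the residual matrix (singular values compared against the
#' `1 - alpha` quantile of column-permuted residuals, stopping at the
#' first non-exceeding component); the surrogate variables are the first K
#' left singular vectors of the residual matrix, hence mutually orthogonal
#' by construction.
#'
#' @param M A [methylation_matrix()].
#' @param covariates Numeric matrix/data frame of model covariates
#'   (excluding the intercept), or NULL.
#' @param n_perm Number of permutations (>= 20).
#' @param seed RNG seed for the permutations.
#' @param alpha Parallel-analysis level (default 0.05).
#' @return List of class `sv_set`: `sv` (samples x K, orthonormal), `K`,
#'   `n_perm`, `alpha`, `seed`.
#' @export
estimate_surrogate_variables <- function(M, covariates = NULL, n_perm = 25,
                                         seed = 1L, alpha = 0.05) {
  stopifnot(inherits(M, "methylation_matrix"))
  if (n_perm < 20) stop("`n_perm` must be >= 20")
  Y <- M$beta
  n <- nrow(Y)
  X <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  if (ncol(X) >= n) stop("more covariates than samples")
  if (qr(X)$rank < ncol(X)) stop("covariate matrix is not full rank")
  qrX <- qr(X)
  R <- Y - X %*% qr.coef(qrX, Y)

  d_obs <- svd(R, nu = 0, nv = 0)$d
  kmax <- length(d_obs)
  d_perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      Rp <- apply(R, 2, sample)
      svd(Rp, nu = 0, nv = 0)$d
    }, numeric(kmax))
  })
  thr <- apply(d_perm, 1, stats::quantile, probs = 1 - alpha, names = FALSE)
  K <- 0L
  for (j in seq_len(kmax)) {
    if (d_obs[j] > thr[j]) K <- j else break
  }
  sv <- if (K > 0) svd(R, nu = K, nv = 0)$u else matrix(0, n, 0)
  structure(list(sv = sv, K = K, n_perm = n_perm, alpha = alpha, seed = seed),
            class = "sv_set")
}

#' Linear EWAS of an exposure
#'
#' Per CpG, the ordinary-least-squares slope of methylation beta on the
#' exposure, adjusting for covariates and surrogate variables, with the
#' homoscedastic SE and a two-sided t P-value (df = n - model columns).
#' Effects are additionally reported as percentage points
#' (`estimate_pct = 100 * estimate`).
#'
#' @param M A [methylation_matrix()].
#' @param exposure Numeric vector (binary coded 0/1 or continuous).
#' @param covariates Optional covariate matrix/data frame.
#' @param svs Optional [estimate_surrogate_variables()] result or matrix.
#' @return Data frame of class `ewas_result` with columns `cpg`, `chrom`,
#'   `pos`, `estimate`, `estimate_pct`, `se`, `p`, `n`, `status`.
#' @export
run_linear_ewas <- function(M, exposure, covariates = NULL, svs = NULL) {
  stopifnot(inherits(M, "methylation_matrix"))
  Y <- M$beta
  n <- nrow(Y)
  if (length(exposure) != n) stop("exposure length does not match samples")
  if (stats::var(exposure) == 0) stop("exposure is constant")
  X <- build_design(n, covariates, svs, extra = cbind(exposure = exposure))
  qrX <- qr(X)
  coefs <- qr.coef(qrX, Y)
  res <- Y - X %*% coefs
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  j <- match("exposure", colnames(X))
  se <- sqrt(sigma2 * XtXinv[j, j])
  est <- coefs[j, ]
  p <- 2 * stats::pt(-abs(est / se), df)
  anno <- M$annotation
  out <- data.frame(
    cpg = anno$cpg, chrom = anno$chrom, pos = anno$pos,
    estimate = unname(est[anno$cpg]), se = unname(se[anno$cpg]),
    p = unname(p[anno$cpg]), n = n, status = "ok",
    stringsAsFactors = FALSE)
  out$estimate_pct <- 100 * out$estimate
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Cox proportional-hazards EWAS of survival
#'
#' Per CpG, the partial-likelihood log hazard per unit methylation beta
#' (Efron tie handling), adjusting for age, sex and surrogate variables
#' (model 1) and additionally for the three prognostic exposures
#' (model 2).  Death from any cause is the failure variable and time to
#' death or censoring in days the time variable.  Non-convergent fits are
#' flagged in the `status` column rather than dropped.
#'
#' @param M A [methylation_matrix()].
#' @param survival_days,event Follow-up time (days) and death flag (0/1).
#' @param covariates Optional covariate matrix/data frame (e.g. age, sex).
#' @param svs Optional surrogate-variable set or matrix.
#' @param model 1 or 2; model 2 requires `exposures`.
#' @param exposures Data frame/matrix with columns `smoking`,
#'   `alcohol_units`, `hpv` (model 2 only).
#' @return An `ewas_result` data frame; `estimate` is the log hazard per
#'   unit beta, P-values use the normal reference for the Wald statistic.
#' @export
run_cox_ewas <- function(M, survival_days, event, covariates = NULL,
                         svs = NULL, model = 1, exposures = NULL) {
  stopifnot(inherits(M, "methylation_matrix"), model %in% c(1, 2))
  n <- nrow(M$beta)
  if (sum(event) == 0) stop("no events: Cox model is degenerate")
  if (sum(event) < 10) stop("fewer than 10 events")
  if (model == 2) {
    if (is.null(exposures) ||
        !all(c("smoking", "alcohol_units", "hpv") %in% colnames(exposures)))
      stop("model 2 requires smoking, alcohol_units and hpv exposures")
    covariates <- cbind(
      if (!is.null(covariates)) as.matrix(covariates),
      as.matrix(exposures[, c("smoking", "alcohol_units", "hpv")]))
  }
  Z <- NULL
  if (!is.null(covariates)) Z <- as.matrix(covariates)
  if (!is.null(svs)) {
    sv <- if (inherits(svs, "sv_set")) svs$sv else as.matrix(svs)
    if (ncol(sv) > 0) Z <- cbind(Z, sv)
  }
  fits <- cox_scan(M$beta, survival_days, event, Z)
  anno <- M$annotation
  out <- data.frame(
    cpg = anno$cpg, chrom = anno$chrom, pos = anno$pos,
    estimate = fits$estimate[anno$cpg], se = fits$se[anno$cpg],
    p = fits$p[anno$cpg], n = n, status = fits$status[anno$cpg],
    stringsAsFactors = FALSE)
  out$estimate_pct <- 100 * out$estimate
  rownames(out) <- NULL
  class(out) <- c("ewas_result", "data.frame")
  out
}

# Shared per-column Cox scan used by the methylation EWAS and SNP GWAS.
cox_scan <- function(Xmat, survival_days, event, Z) {
  surv <- survival::Surv(survival_days, event)
  m <- ncol(Xmat)
  estimate <- se <- p <- rep(NA_real_, m)
  status <- rep("ok", m)
  names(estimate) <- names(se) <- names(p) <- names(status) <- colnames(Xmat)
  for (j in seq_len(m)) {
    x <- Xmat[, j]
    if (stats::var(x) == 0) {
      status[j] <- "monomorphic"
      next
    }
    dat <- if (is.null(Z)) data.frame(x = x) else data.frame(x = x, Z)
    fit <- NULL
    warned <- FALSE
    fit <- tryCatch(
      withCallingHandlers(
        survival::coxph(surv ~ ., data = dat, ties = "efron"),
        warning = function(w) {
          warned <<- TRUE
          invokeRestart("muffleWarning")
        }),
      error = function(e) NULL)
    if (is.null(fit) || is.na(stats::coef(fit)[["x"]])) {
      status[j] <- "failed"
      next
    }
    estimate[j] <- stats::coef(fit)[["x"]]
    se[j] <- sqrt(stats::vcov(fit)["x", "x"])
    p[j] <- z_pvalue(estimate[j], se[j])
    if (warned) status[j] <- "nonconverged"
  }
  list(estimate = estimate, se = se, p = p, status = status)
}

#' Per-SNP Cox survival GWAS on additive dosages
#'
#' One Cox proportional-hazards fit per SNP, additive in the effect-allele
#' dosage, adjusting for age at diagnosis and sex.  Monomorphic SNPs are
#' returned as flagged records with missing estimates.
#'
#' @param dosage Samples x SNPs dosage matrix in \[0, 2\] (named columns).
#' @param survival_days,event Follow-up time and death flag.
#' @param age,sex Covariates.
#' @param effect_allele Optional character vector of effect alleles
#'   (recycled), recorded for downstream harmonisation.
#' @return Data frame of class `snp_survival` with columns `snp`,
#'   `effect_allele`, `loghr`, `se`, `p`, `n_events`, `status`.
#' @export
run_snp_survival_gwas <- function(dosage, survival_days, event, age, sex,
                                  effect_allele = "A") {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) == 0) {
    out <- data.frame(snp = character(), effect_allele = character(),
                      loghr = numeric(), se = numeric(), p = numeric(),
                      n_events = integer(), status = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("snp_survival", "data.frame")
    return(out)
  }
  if (any(dosage < 0 | dosage > 2)) stop("dosages must lie in [0, 2]")
  if (sum(event) < 10) stop("fewer than 10 events")
  fits <- cox_scan(dosage, survival_days, event, cbind(age = age, sex = sex))
  out <- data.frame(
    snp = colnames(dosage),
    effect_allele = rep_len(effect_allele, ncol(dosage)),
    loghr = unname(fits$estimate), se = unname(fits$se), p = unname(fits$p),
    n_events = sum(event), status = unname(fits$status),
    stringsAsFactors = FALSE)
  class(out) <- c("snp_survival", "data.frame")
  out
}

#' Bonferroni threshold with printed-mantissa truncation
#'
#' Returns `alpha / m` with the mantissa truncated to one decimal place,
#' the display convention used for genome-wide methylation thresholds
#' (0.05 / 862491 prints as 5.7e-8).  The untruncated ratio is attached
#' as attribute `raw`.
#'
#' @param alpha Family-wise error level in (0, 1).
#' @param m Number of tests (>= 1).
#' @return The truncated threshold, with attribute `raw`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  if (m < 1) stop("`m` must be >= 1")
  raw <- alpha / m
  e <- floor(log10(raw))
  mantissa <- raw / 10^e
  trunc_m <- floor(mantissa * 10 + 1e-9) / 10
  structure(trunc_m * 10^e, raw = raw)
}

#' Suggestive significance threshold
#'
#' The fixed 2.4e-7 constant used as the suggestive evidence threshold
#' (the level derived for the 450K predecessor array).
#' @export
suggestive_threshold <- function() 2.4e-7

#' Correlation of surrogate variables with an external covariate
#'
#' Pearson correlation and P-value of each surrogate variable with the
#' covariate, plus the joint variance explained (R-squared of regressing
#' the covariate on all SVs).  SVs with P < 0.05 are listed.
#'
#' @param svs An `sv_set` or a samples x K matrix.
#' @param covariate Numeric vector, one value per sample.
#' @return List with `table` (sv, r, p), `r_squared`, `flagged`.
#' @export
sv_sensitivity <- function(svs, covariate) {
  sv <- if (inherits(svs, "sv_set")) svs$sv else as.matrix(svs)
  if (nrow(sv) != length(covariate))
    stop("covariate length does not match samples")
  if (stats::var(covariate) == 0) stop("covariate is constant")
  K <- ncol(sv)
  if (K == 0)
    return(list(table = data.frame(sv = character(), r = numeric(),
                                   p = numeric()),
                r_squared = 0, flagged = character()))
  tab <- do.call(rbind, lapply(seq_len(K), function(k) {
    ct <- stats::cor.test(sv[, k], covariate)
    data.frame(sv = sprintf("SV%d", k), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  }))
  res <- stats::lm.fit(cbind(1, sv), covariate)$residuals
  r2 <- 1 - sum(res^2) / sum((covariate - mean(covariate))^2)
  list(table = tab, r_squared = r2, flagged = tab$sv[tab$p < 0.05])
}
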