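# Differentially methylated region calling from EWAS summary statistics:
# candidate detection, correlation-aware GLS combination of per-CpG
# effects, sub-window scan, and Sidak adjustment.

#' Find candidate regions from an EWAS result
#'
#' Maximal runs of consecutive CpGs (in genomic order) that all reach
#' nominal significance (`p < p_enter`), share the sign of the effect,
#' and are separated by at most `max_gap` bp.  Singletons are discarded:
#' a region needs more than one CpG.
#'
#' @param ewas An `ewas_result` data frame (must carry `chrom`, `pos`).
#' @param p_enter Per-CpG entry threshold (default 0.05).
#' @param max_gap Maximum gap between adjacent members in bp (default 500).
#' @return List of `candidate_region` lists (`chrom`, `start`, `end`,
#'   `cpgs` in positional order).
#' @export
find_candidate_regions <- function(ewas, p_enter = 0.05, max_gap = 500) {
  stopifnot(is.data.frame(ewas))
  un <- is.na(ewas$chrom) | is.na(ewas$pos)
  if (any(un))
    stop(sprintf("unannotated CpGs: %s", paste(ewas$cpg[un], collapse = ", ")))
  ew <- ewas[order(ewas$chrom, ewas$pos), , drop = FALSE]
  ok <- ew$status == "ok" & !is.na(ew$p)
  qual <- ok & ew$p < p_enter
  sgn <- sign(ew$estimate)

  out <- list()
  run <- integer(0)
  flush <- function(run) {
    if (length(run) >= 2) {
      out[[length(out) + 1L]] <<- structure(
        list(chrom = ew$chrom[run[1]], start = ew$pos[run[1]],
             end = ew$pos[run[length(run)]], cpgs = ew$cpg[run]),
        class = "candidate_region")
    }
  }
  for (i in seq_len(nrow(ew))) {
    if (!qual[i]) { flush(run); run <- integer(0); next }
    if (length(run) > 0) {
      prev <- run[length(run)]
      brk <- ew$chrom[i] != ew$chrom[prev] ||
        (ew$pos[i] - ew$pos[prev]) > max_gap ||
        sgn[i] != sgn[prev]
      if (brk) { flush(run); run <- integer(0) }
    }
    run <- c(run, i)
  }
  flush(run)
  out
}

#' Residualised CpG correlation matrix
#'
#' Pearson correlation of methylation at the given CpGs after removing
#' the model covariates — the error-correlation estimate the combined
#' regional SE requires.
#'
#' @param M A [methylation_matrix()].
#' @param cpgs CpG ids (columns of `M`).
#' @param covariates Optional covariate matrix (intercept always removed).
#' @return Correlation matrix with the CpGs as dimnames.
#' @export
residual_cor <- function(M, cpgs, covariates = NULL) {
  stopifnot(inherits(M, "methylation_matrix"))
  missing <- setdiff(cpgs, colnames(M$beta))
  if (length(missing))
    stop(sprintf("CpGs absent from methylation matrix: %s",
                 paste(missing, collapse = ", ")))
  Y <- M$beta[, cpgs, drop = FALSE]
  X <- cbind(rep(1, nrow(Y)), if (!is.null(covariates)) as.matrix(covariates))
  R <- Y - X %*% qr.coef(qr(X), Y)
  stats::cor(R)
}

#' GLS combination of per-CpG effects over a region
#'
#' With member estimates b, SEs s and correlation matrix R, the combined
#' effect is the generalised-least-squares mean under
#' V = diag(s) R diag(s): `beta = (1' V^-1 b) / (1' V^-1 1)`,
#' `SE = (1' V^-1 1)^-1/2`, with a two-sided normal P-value.  A ridge of
#' 1e-6 is added to R's diagonal if V is not positive definite; a still
#' singular V is an error.  With R = I this is classical fixed-effect
#' inverse-variance meta-analysis.
#'
#' @param region A `candidate_region` (or list with `chrom`, `start`,
#'   `end`, `cpgs`).
#' @param ewas The `ewas_result` the members came from.
#' @param R Correlation matrix covering the member CpGs.
#' @return One-row data frame of class `dmr_record`: `chrom`, `start`,
#'   `end`, `n_cpg`, `cpgs`, `estimate`, `se`, `z`, `p`.
#' @export
region_statistic <- function(region, ewas, R) {
  cpgs <- region$cpgs
  idx <- match(cpgs, ewas$cpg)
  if (anyNA(idx))
    stop(sprintf("region CpGs absent from EWAS: %s",
                 paste(cpgs[is.na(idx)], collapse = ", ")))
  if (!all(cpgs %in% rownames(R)))
    stop("region CpGs absent from correlation matrix")
  b <- ewas$estimate[idx]
  s <- ewas$se[idx]
  Rsub <- R[cpgs, cpgs, drop = FALSE]
  ch <- chol_with_ridge(s, Rsub)
  ones <- rep(1, length(b))
  w <- chol_solve(ch$chol, ones)
  denom <- sum(w)
  est <- sum(w * b) / denom
  se <- denom^(-0.5)
  z <- est / se
  out <- data.frame(chrom = region$chrom, start = region$start,
                    end = region$end, n_cpg = length(cpgs),
                    cpgs = paste(cpgs, collapse = ","),
                    estimate = est, se = se, z = z, p = z_pvalue(est, se),
                    stringsAsFactors = FALSE)
  class(out) <- c("dmr_record", "data.frame")
  out
}

# Size of the Sidak universe: every contiguous run of >= 2 CpGs whose
# inter-CpG gaps are all <= max_gap contributes L(L-1)/2 windows, where L
# is the run length.  CpGs without a usable P (failed fits) are excluded.
count_eligible_windows <- function(ewas, max_gap) {
  ew <- ewas[!is.na(ewas$p), , drop = FALSE]
  ew <- ew[order(ew$chrom, ew$pos), , drop = FALSE]
  if (nrow(ew) < 2) return(0L)
  brk <- c(TRUE, ew$chrom[-1] != ew$chrom[-nrow(ew)] |
                 diff(ew$pos) > max_gap)
  runs <- tabulate(cumsum(brk))
  as.integer(sum(runs * (runs - 1) / 2))
}

#' Sidak multiple-testing adjustment
#'
#' `p_adj = 1 - (1 - p)^T`, clipped to (0, 1\]; computed via `expm1` so
#' tiny P-values do not underflow.
#'
#' @param p P-values in (0, 1].
#' @param T Number of tests in the adjustment universe (>= 1).
#' @return Adjusted P-values.
#' @export
sidak_adjust <- function(p, T) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  if (T < 1) stop("T must be >= 1")
  pmin(1, -expm1(T * log1p(-p)))
}

#' Call differentially methylated regions
#'
#' Scans every contiguous sub-window (length >= 2) of every candidate
#' region, scores it with [region_statistic()] under the residualised CpG
#' correlation, and keeps the best-P sub-window per candidate.  The Sidak
#' adjustment uses T = the number of gap-eligible windows genome-wide
#' (every contiguous run of >= 2 CpGs whose inter-CpG gaps are all
#' <= `max_gap`, irrespective of their P-values): because candidates are
#' selected for uniformly small member P-values, their best-window P is
#' conditionally small, and a universe restricted to evaluated windows
#' would not correct the implicit genome-wide scan.  Significant regions
#' have `p_adj < alpha`.
#'
#' @param ewas An `ewas_result`.
#' @param M The [methylation_matrix()] the EWAS was run on.
#' @param covariates Covariates used to residualise methylation before
#'   computing the CpG correlation (should mirror the EWAS model).
#' @param p_enter,max_gap Candidate-detection parameters.
#' @param alpha Regional significance level on the Sidak-adjusted P.
#' @return Data frame of class `dmr_table` (one row per candidate, best
#'   sub-window): `chrom`, `start`, `end`, `n_cpg`, `cpgs`, `estimate`,
#'   `se`, `z`, `p`, `p_adj`, `significant`; the Sidak universe size in
#'   attribute `n_windows`.
#' @export
call_dmrs <- function(ewas, M, covariates = NULL, p_enter = 0.05,
                      max_gap = 500, alpha = 0.05) {
  cands <- find_candidate_regions(ewas, p_enter, max_gap)
  n_windows <- count_eligible_windows(ewas, max_gap)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_cpg = integer(), cpgs = character(),
                      estimate = numeric(), se = numeric(), z = numeric(),
                      p = numeric(), p_adj = numeric(),
                      significant = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("dmr_table", "data.frame")
  if (length(cands) == 0) return(structure(empty, n_windows = n_windows))

  best <- vector("list", length(cands))
  for (ci in seq_along(cands)) {
    cand <- cands[[ci]]
    cpgs <- cand$cpgs
    R <- residual_cor(M, cpgs, covariates)
    pos <- M$annotation$pos[match(cpgs, M$annotation$cpg)]
    k <- length(cpgs)
    rows <- list()
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      sub <- structure(list(chrom = cand$chrom, start = pos[i], end = pos[j],
                            cpgs = cpgs[i:j]), class = "candidate_region")
      rows[[length(rows) + 1L]] <- region_statistic(sub, ewas, R)
    }
    tab <- do.call(rbind, rows)
    best[[ci]] <- tab[which.min(tab$p), , drop = FALSE]
  }
  out <- do.call(rbind, best)
  out$p_adj <- sidak_adjust(out$p, max(1L, n_windows))
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_table", "data.frame")
  structure(out, n_windows = n_windows)
}
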