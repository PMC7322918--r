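# Exposure/survival DMR overlap and genetic-instrument construction:
# mQTL filtering, iterative per-CpG LD clumping, and REML meta-analysis
# of each SNP's CpG effects to a region-average effect (beta_GP).

#' Intersect exposure DMRs with survival DMRs
#'
#' Regions are paired when their genomic intervals intersect on the same
#' chromosome; the shared CpGs are the intersection of the member lists.
#' The sentinel is the shared CpG with the lowest exposure-EWAS P-value
#' (ties broken by lowest position).  Both tables are filtered to
#' `p_adj < alpha` before pairing.
#'
#' @param exposure_dmrs,survival_dmrs `dmr_table` data frames.
#' @param exposure_ewas The exposure `ewas_result` (for sentinel choice).
#' @param exposure Label recorded on each shared region.
#' @param alpha Regional significance filter (default 0.05).
#' @return List of `shared_region` objects (possibly empty).
#' @export
overlap_dmrs <- function(exposure_dmrs, survival_dmrs, exposure_ewas,
                         exposure = "exposure", alpha = 0.05) {
  ed <- exposure_dmrs[exposure_dmrs$p_adj < alpha, , drop = FALSE]
  sd_ <- survival_dmrs[survival_dmrs$p_adj < alpha, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(ed))) for (j in seq_len(nrow(sd_))) {
    if (ed$chrom[i] != sd_$chrom[j]) next
    if (ed$start[i] > sd_$end[j] || sd_$start[j] > ed$end[i]) next
    ec <- strsplit(ed$cpgs[i], ",", fixed = TRUE)[[1]]
    sc <- strsplit(sd_$cpgs[j], ",", fixed = TRUE)[[1]]
    shared <- intersect(ec, sc)
    if (length(shared) == 0) next
    idx <- match(shared, exposure_ewas$cpg)
    if (anyNA(idx))
      stop(sprintf("shared CpGs absent from exposure EWAS: %s",
                   paste(shared[is.na(idx)], collapse = ", ")))
    ord <- order(exposure_ewas$p[idx], exposure_ewas$pos[idx])
    shared <- shared[ord]
    out[[length(out) + 1L]] <- structure(
      list(exposure = exposure, chrom = ed$chrom[i],
           start = max(ed$start[i], sd_$start[j]),
           end = min(ed$end[i], sd_$end[j]),
           exposure_dmr = ed[i, , drop = FALSE],
           survival_dmr = sd_[j, , drop = FALSE],
           shared_cpgs = shared, sentinel = shared[1]),
      class = "shared_region")
  }
  out
}

#' Filter mQTL records for instrument construction
#'
#' Restricts the summary table to the given CpGs and applies the
#' instrument filters: minor-allele frequency strictly above `maf_min`
#' (MAF = min(eaf, 1 - eaf)) and P strictly below `p_max`.
#'
#' @param mqtls Data frame with columns `snp`, `cpg`, `beta`, `se`, `p`,
#'   `eaf` (and allele columns).
#' @param cpgs CpG ids to retain.
#' @param maf_min MAF filter, strict `>` (default 0.05).
#' @param p_max P filter, strict `<` (default 5e-8).
#' @return Filtered mQTL data frame.
#' @export
filter_mqtls <- function(mqtls, cpgs, maf_min = 0.05, p_max = 5e-8) {
  maf <- pmin(mqtls$eaf, 1 - mqtls$eaf)
  # strict > with a guard for floating-point residue (1 - 0.95 > 0.05
  # is TRUE in doubles; the boundary must be excluded)
  keep <- mqtls$cpg %in% cpgs & maf - maf_min > 1e-12 & mqtls$p < p_max
  out <- mqtls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the lowest-P unprocessed SNP and discards every SNP
#' with squared correlation `r^2 >= r2_max` against it.  P-ties are
#' broken by lexicographic SNP id, making the selection deterministic and
#' invariant to input row order.
#'
#' @param snps Data frame with columns `snp` and `p`.
#' @param ld Signed correlation matrix covering all SNPs (dimnames).
#' @param r2_max Clumping threshold on r-squared (default 0.01).
#' @return Character vector of kept SNP ids, in selection order.
#' @export
clump_snps <- function(snps, ld, r2_max = 0.01) {
  if (nrow(snps) == 0) return(character(0))
  missing <- setdiff(snps$snp, rownames(ld))
  if (length(missing))
    stop(sprintf("SNPs missing from LD matrix: %s",
                 paste(missing, collapse = ", ")))
  pool <- snps[order(snps$p, snps$snp), , drop = FALSE]
  kept <- character(0)
  while (nrow(pool) > 0) {
    lead <- pool$snp[1]
    kept <- c(kept, lead)
    r2 <- ld[lead, pool$snp]^2
    pool <- pool[r2 < r2_max, , drop = FALSE]
  }
  kept
}

#' Iterative per-CpG instrument selection for a shared region
#'
#' Walks the shared CpGs in ascending exposure-EWAS P starting at the
#' sentinel.  At each step the mQTLs of the current CpG that are not
#' already associated (present at the genome-wide filter) with any
#' earlier CpG of the region are clumped at `r2_max` and appended to the
#' running set; the final set is deduplicated by SNP id.
#'
#' @param region A `shared_region` from [overlap_dmrs()].
#' @param mqtls mQTL summary table (filtered or raw; the instrument
#'   filters are applied internally).
#' @param ld Signed LD matrix covering the candidate SNPs.
#' @param exposure_ewas The exposure `ewas_result` (CpG ordering).
#' @param maf_min,p_max,r2_max Filters; see [filter_mqtls()] and
#'   [clump_snps()].
#' @return Data frame with columns `snp`, `cpg` (source CpG), `step`
#'   (selection step), in selection order; zero rows (with attribute
#'   `skipped = TRUE`) when no mQTL passes the filters.
#' @export
build_instrument <- function(region, mqtls, ld, exposure_ewas,
                             maf_min = 0.05, p_max = 5e-8, r2_max = 0.01) {
  stopifnot(inherits(region, "shared_region"))
  mq <- filter_mqtls(mqtls, region$shared_cpgs, maf_min, p_max)
  empty <- data.frame(snp = character(), cpg = character(), step = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(mq) == 0) return(structure(empty, skipped = TRUE))

  idx <- match(region$shared_cpgs, exposure_ewas$cpg)
  cpg_order <- region$shared_cpgs[order(exposure_ewas$p[idx],
                                        region$shared_cpgs)]
  selected <- empty
  earlier <- character(0)
  for (k in seq_along(cpg_order)) {
    ck <- cpg_order[k]
    assoc_earlier <- unique(mq$snp[mq$cpg %in% earlier])
    cand <- mq[mq$cpg == ck & !(mq$snp %in% assoc_earlier), , drop = FALSE]
    if (nrow(cand) > 0) {
      kept <- clump_snps(cand[, c("snp", "p")], ld, r2_max)
      if (length(kept))
        selected <- rbind(selected,
                          data.frame(snp = kept, cpg = ck, step = k,
                                     stringsAsFactors = FALSE))
    }
    earlier <- c(earlier, ck)
  }
  selected <- selected[!duplicated(selected$snp), , drop = FALSE]
  rownames(selected) <- NULL
  if (nrow(selected) == 0) attr(selected, "skipped") <- TRUE
  selected
}

#' REML meta-analysis of one SNP's CpG effects to a region-average effect
#'
#' Model: y = 1 mu + eps with eps ~ N(0, V + tau2 I), where
#' V = diag(se) R diag(se) and R is the pairwise correlation of the
#' proxied CpGs.  tau2 >= 0 is estimated by one-dimensional bounded
#' optimisation of the restricted log-likelihood (tolerance 1e-8); the
#' combined effect is the GLS mean `mu = (1'W1)^-1 1'Wy` with
#' W = (V + tau2 I)^-1 and `se_gp = (1'W1)^-1/2`.  mu is interpreted as
#' the SNP's effect on average methylation across the region (beta_GP).
#' A single CpG returns its own effect with tau2 = 0.
#'
#' @param beta,se Per-CpG mQTL effects and SEs for one SNP.
#' @param R Correlation matrix of the proxied CpGs.
#' @param tol Optimisation tolerance.
#' @return List: `beta_gp`, `se_gp`, `tau2`.
#' @export
reml_meta_dmr_effect <- function(beta, se, R, tol = 1e-8) {
  k <- length(beta)
  stopifnot(length(se) == k, all(se > 0))
  if (k == 1) return(list(beta_gp = beta, se_gp = se, tau2 = 0))
  ch0 <- chol_with_ridge(se, R)  # errors if non-PSD after ridge repair
  V <- ch0$V
  ones <- rep(1, k)

  restricted_nll <- function(tau2) {
    S <- V + diag(tau2, k)
    ch <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(ch)) return(Inf)
    Si1 <- chol_solve(ch, ones)
    Siy <- chol_solve(ch, beta)
    s11 <- sum(Si1)
    mu <- sum(Si1 * beta) / s11
    quad <- sum(beta * Siy) - s11 * mu^2
    0.5 * (2 * sum(log(diag(ch))) + log(s11) + quad)
  }

  upper <- max(10 * stats::var(beta), 10 * max(se)^2, 1e-6)
  opt <- stats::optimize(restricted_nll, c(0, upper), tol = tol)
  tau2 <- if (restricted_nll(0) <= opt$objective) 0 else opt$minimum

  S <- V + diag(tau2, k)
  ch <- chol(S)
  Si1 <- chol_solve(ch, ones)
  s11 <- sum(Si1)
  list(beta_gp = sum(Si1 * beta) / s11, se_gp = s11^(-0.5), tau2 = tau2)
}

#' Build the full instrument set for a shared region
#'
#' Runs [build_instrument()] and then, for every selected SNP,
#' REML-combines its effects across all region CpGs it proxies into a
#' region-average effect `beta_gp` with `se_gp` via
#' [reml_meta_dmr_effect()].  The sentinel CpG's own mQTL effect is
#' carried along for the sentinel-only sensitivity analysis.
#'
#' @inheritParams build_instrument
#' @param cpg_cor Correlation matrix of the region CpGs (e.g. from
#'   [residual_cor()] on the reference panel).
#' @return List of class `instrument_set`: `region`, `sentinel`,
#'   `snps` (snp, effect_allele, other_allele, eaf, beta_gp, se_gp, tau2,
#'   n_cpg, cpg_trail, sentinel_beta, sentinel_se), and the filtered
#'   `mqtls` sub-table.  Attribute `skipped = TRUE` when empty.
#' @export
build_instrument_set <- function(region, mqtls, ld, exposure_ewas, cpg_cor,
                                 maf_min = 0.05, p_max = 5e-8,
                                 r2_max = 0.01) {
  sel <- build_instrument(region, mqtls, ld, exposure_ewas,
                          maf_min, p_max, r2_max)
  mq <- filter_mqtls(mqtls, region$shared_cpgs, maf_min, p_max)
  snps <- data.frame(
    snp = character(), effect_allele = character(),
    other_allele = character(), eaf = numeric(), beta_gp = numeric(),
    se_gp = numeric(), tau2 = numeric(), n_cpg = integer(),
    cpg_trail = character(), sentinel_beta = numeric(),
    sentinel_se = numeric(), stringsAsFactors = FALSE)
  for (s in sel$snp) {
    rows <- mq[mq$snp == s, , drop = FALSE]
    rows <- rows[order(rows$cpg), , drop = FALSE]
    fit <- reml_meta_dmr_effect(rows$beta, rows$se,
                                cpg_cor[rows$cpg, rows$cpg, drop = FALSE])
    si <- match(region$sentinel, rows$cpg)
    snps <- rbind(snps, data.frame(
      snp = s, effect_allele = rows$effect_allele[1],
      other_allele = rows$other_allele[1], eaf = rows$eaf[1],
      beta_gp = fit$beta_gp, se_gp = fit$se_gp, tau2 = fit$tau2,
      n_cpg = nrow(rows), cpg_trail = paste(rows$cpg, collapse = ","),
      sentinel_beta = if (is.na(si)) NA_real_ else rows$beta[si],
      sentinel_se = if (is.na(si)) NA_real_ else rows$se[si],
      stringsAsFactors = FALSE))
  }
  rownames(snps) <- NULL
  out <- structure(list(region = region, sentinel = region$sentinel,
                        snps = snps, mqtls = mq, selection = sel),
                   class = "instrument_set")
  if (nrow(snps) == 0) attr(out, "skipped") <- TRUE
  out
}

# ---- reference-panel summary statistics ----------------------------------

#' Per-SNP, per-CpG mQTL summary statistics from the reference panel
#'
#' Simple OLS of each region CpG on each region SNP dosage (marginal
#' model, unrelated individuals), yielding the mQTL summary table the
#' instrument builder consumes.  Effect alleles are the counted dosage
#' allele (synthetic labels A/G, deliberately non-palindromic).
#'
#' @param panel A `panel_data` from [simulate_reference_panel()].
#' @return Data frame with columns `snp`, `cpg`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#' @export
panel_mqtls <- function(panel) {
  stopifnot(inherits(panel, "panel_data"))
  anno <- panel$methylation$annotation
  snps <- panel$truth$snps
  out <- list()
  n <- nrow(panel$dosage)
  for (r in unique(snps$region)) {
    sid <- snps$snp[snps$region == r]
    cid <- anno$cpg[!is.na(anno$region) & anno$region == r]
    D <- panel$dosage[, sid, drop = FALSE]
    Y <- panel$methylation$beta[, cid, drop = FALSE]
    Dc <- sweep(D, 2, colMeans(D))
    Yc <- sweep(Y, 2, colMeans(Y))
    ssd <- colSums(Dc^2)
    ssy <- colSums(Yc^2)
    cross <- crossprod(Dc, Yc)              # snps x cpgs
    slope <- sweep(cross, 1, ssd, "/")
    sse <- -sweep(slope^2, 1, ssd, "*")
    sse <- sweep(sse, 2, ssy, "+")
    sse[sse < 0] <- 0
    se <- sqrt(sweep(sse / (n - 2), 1, ssd, "/"))
    tstat <- slope / se
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    eaf <- colMeans(D) / 2
    out[[length(out) + 1L]] <- data.frame(
      snp = rep(sid, times = length(cid)),
      cpg = rep(cid, each = length(sid)),
      effect_allele = "A", other_allele = "G",
      eaf = rep(unname(eaf), times = length(cid)),
      beta = as.vector(slope), se = as.vector(se), p = as.vector(p),
      n = n, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Signed, allele-aligned LD matrix from panel genotypes
#'
#' Empirical Pearson correlation of the additive dosages, giving the
#' signed r the correlation-adjusted MR estimators require (public LD
#' services report only unsigned r-squared).
#'
#' @param panel A `panel_data`.
#' @param snps Optional SNP ids to restrict to.
#' @return Correlation matrix with SNP-id dimnames.
#' @export
panel_ld <- function(panel, snps = NULL) {
  stopifnot(inherits(panel, "panel_data"))
  D <- panel$dosage
  if (!is.null(snps)) {
    missing <- setdiff(snps, colnames(D))
    if (length(missing))
      stop(sprintf("SNPs absent from panel: %s",
                   paste(missing, collapse = ", ")))
    D <- D[, snps, drop = FALSE]
  }
  stats::cor(D)
}
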