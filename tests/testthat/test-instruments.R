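mk_dmr <- function(chrom, start, end, cpgs, p_adj = 0.01) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             n_cpg = length(strsplit(cpgs, ",")[[1]]), cpgs = cpgs,
             estimate = 0.02, se = 0.005, p = 1e-6, p_adj = p_adj,
             stringsAsFactors = FALSE)
}

mk_expo_ewas <- function(cpg, pos, p) {
  data.frame(cpg = cpg, chrom = "chr1", pos = as.integer(pos),
             estimate = 0.02, se = 0.005, p = p, n = 100L, status = "ok",
             stringsAsFactors = FALSE)
}

test_that("DMR overlap pairs intersecting intervals and picks the
           min-P sentinel", {
  ew <- mk_expo_ewas(c("a", "b", "c", "d"), c(1000, 1600, 1900, 2400),
                     p = c(1e-4, 1e-6, 1e-5, 1e-3))
  # disjoint intervals: no shared regions
  expect_length(
    overlap_dmrs(mk_dmr("chr1", 1000, 2000, "a,b,c"),
                 mk_dmr("chr1", 5000, 6000, "d"), ew), 0)
  # worked intersection: shared CpGs {b, c}
  sh <- overlap_dmrs(mk_dmr("chr1", 1000, 2000, "a,b,c"),
                     mk_dmr("chr1", 1500, 2500, "b,c,d"), ew)
  expect_length(sh, 1)
  expect_setequal(sh[[1]]$shared_cpgs, c("b", "c"))
  expect_identical(sh[[1]]$sentinel, "b")  # lowest exposure P
  # identical single region in both tables: full member list shared
  sh2 <- overlap_dmrs(mk_dmr("chr1", 1000, 2000, "a,b,c"),
                      mk_dmr("chr1", 1000, 2000, "a,b,c"), ew)
  expect_setequal(sh2[[1]]$shared_cpgs, c("a", "b", "c"))
  expect_identical(sh2[[1]]$sentinel, "b")
  # non-significant regions are filtered before pairing
  expect_length(
    overlap_dmrs(mk_dmr("chr1", 1000, 2000, "a,b", p_adj = 0.2),
                 mk_dmr("chr1", 1000, 2000, "a,b"), ew), 0)
})

test_that("mQTL filters are strict inequalities on MAF and P", {
  mq <- data.frame(
    snp = c("s1", "s2", "s3", "s4"), cpg = "c1",
    effect_allele = "A", other_allele = "G",
    eaf = c(0.95, 0.3, 0.3, 0.3),
    beta = 0.1, se = 0.01,
    p = c(1e-10, 5e-8, 4.9e-8, 1e-10), stringsAsFactors = FALSE)
  kept <- filter_mqtls(mq, "c1")
  # eaf 0.95 -> MAF exactly 0.05 -> excluded; P exactly 5e-8 -> excluded
  expect_setequal(kept$snp, c("s3", "s4"))
  expect_identical(nrow(filter_mqtls(mq[0, ], "c1")), 0L)
  expect_identical(nrow(filter_mqtls(mq, "other_cpg")), 0L)
})

test_that("greedy clumping keeps lead SNPs and is deterministic", {
  ld <- diag(3)
  dimnames(ld) <- list(c("s1", "s2", "s3"), c("s1", "s2", "s3"))
  expect_identical(clump_snps(data.frame(snp = "s1", p = 1e-9), ld), "s1")
  # two SNPs at r2 = 0.5: only the smaller-P one survives
  ld2 <- ld; ld2["s1", "s2"] <- ld2["s2", "s1"] <- sqrt(0.5)
  expect_identical(
    clump_snps(data.frame(snp = c("s1", "s2"), p = c(1e-10, 1e-9)), ld2),
    "s1")
  # three mutually independent SNPs all survive
  expect_setequal(
    clump_snps(data.frame(snp = c("s1", "s2", "s3"),
                          p = c(1e-8, 1e-9, 1e-10)), ld),
    c("s1", "s2", "s3"))
  # ties broken lexicographically; missing SNP is an error naming it
  expect_identical(
    clump_snps(data.frame(snp = c("s2", "s1"), p = c(1e-9, 1e-9)), ld2),
    "s1")
  expect_error(clump_snps(data.frame(snp = "zz", p = 0.01), ld), "zz")
})

toy_region <- function() {
  structure(list(exposure = "smoking", chrom = "chr1", start = 1000L,
                 end = 2000L, shared_cpgs = c("c1", "c2"), sentinel = "c1"),
            class = "shared_region")
}

toy_mqtls <- function() {
  data.frame(
    snp = c("s1", "s2", "s3", "s3", "s4"),
    cpg = c("c1", "c1", "c1", "c2", "c2"),
    effect_allele = "A", other_allele = "G", eaf = 0.3,
    beta = c(0.10, 0.09, 0.08, 0.07, 0.06), se = 0.01,
    p = c(1e-10, 1e-9, 1e-9, 1e-12, 1e-11),
    stringsAsFactors = FALSE)
}

toy_ld <- function() {
  ld <- diag(4)
  dimnames(ld) <- list(c("s1", "s2", "s3", "s4"),
                       c("s1", "s2", "s3", "s4"))
  ld["s1", "s2"] <- ld["s2", "s1"] <- sqrt(0.5)
  ld
}

toy_expo_ewas <- function() mk_expo_ewas(c("c1", "c2"), c(1100, 1300),
                                         p = c(1e-6, 1e-5))

test_that("iterative instrument selection follows the manual trace", {
  # step 1 (sentinel c1): candidates s1, s2, s3; clump keeps s1 (lead),
  # drops s2 (r2 = 0.5 with s1), keeps s3 (independent).
  # step 2 (c2): s3 already associated with c1, so only s4 enters.
  sel <- build_instrument(toy_region(), toy_mqtls(), toy_ld(),
                          toy_expo_ewas())
  expect_identical(sel$snp, c("s1", "s3", "s4"))
  expect_identical(sel$cpg, c("c1", "c1", "c2"))
  expect_identical(sel$step, c(1L, 1L, 2L))
})

test_that("a one-CpG region reduces to clump(filter(mqtls))", {
  reg <- toy_region()
  reg$shared_cpgs <- "c1"
  sel <- build_instrument(reg, toy_mqtls(), toy_ld(), toy_expo_ewas())
  mq <- filter_mqtls(toy_mqtls(), "c1")
  expect_identical(sel$snp, clump_snps(mq[, c("snp", "p")], toy_ld()))
})

test_that("instrument selection is invariant to input row order", {
  mq <- toy_mqtls()
  sel0 <- build_instrument(toy_region(), mq, toy_ld(), toy_expo_ewas())
  for (s in 1:5) {
    perm <- with_seed(s, mq[sample(nrow(mq)), ])
    expect_identical(
      build_instrument(toy_region(), perm, toy_ld(), toy_expo_ewas()),
      sel0)
  }
})

test_that("a region with no passing mQTLs is flagged as skipped", {
  mq <- toy_mqtls()
  mq$p <- 0.5
  sel <- build_instrument(toy_region(), mq, toy_ld(), toy_expo_ewas())
  expect_identical(nrow(sel), 0L)
  expect_true(isTRUE(attr(sel, "skipped")))
})

test_that("REML meta-analysis has its degenerate closed forms", {
  # single CpG: pass-through
  one <- reml_meta_dmr_effect(0.08, 0.02, matrix(1, 1, 1))
  expect_identical(one, list(beta_gp = 0.08, se_gp = 0.02, tau2 = 0))
  # identical effects, independent errors, tau2 = 0: fixed-effect mean
  two <- reml_meta_dmr_effect(c(0.1, 0.1), c(0.02, 0.02), diag(2))
  expect_equal(two$beta_gp, 0.1, tolerance = 1e-10)
  expect_equal(two$se_gp, 0.02 / sqrt(2), tolerance = 1e-6)
  expect_equal(two$tau2, 0, tolerance = 1e-8)
})

test_that("REML matches a tau2 grid-search oracle", {
  R <- matrix(c(1, 0.6, 0.6, 1), 2, 2)
  got <- reml_meta_dmr_effect(c(0.08, 0.12), c(0.02, 0.03), R)
  want <- oracle_reml_grid(c(0.08, 0.12), c(0.02, 0.03), R, upper = 0.01)
  expect_lt(abs(got$beta_gp - want$mu), 1e-6)
  expect_lt(abs(got$tau2 - want$tau2), 2e-6)
  expect_lt(abs(got$se_gp - want$se), 1e-5)
})

test_that("REML agrees with an established mixed-model meta-analysis", {
  skip_if_not_installed("metafor")
  with_seed(91, {
    for (i in 1:5) {
      k <- sample(2:4, 1)
      y <- rnorm(k, 0.1, 0.05)
      s <- runif(k, 0.01, 0.03)
      R <- matrix(0.4, k, k); diag(R) <- 1
      V <- diag(s) %*% R %*% diag(s)
      got <- reml_meta_dmr_effect(y, s, R)
      fit <- suppressWarnings(metafor::rma.mv(
        yi = y, V = V, random = ~ 1 | unit,
        data = data.frame(unit = seq_len(k)), method = "REML"))
      expect_equal(got$beta_gp, unname(fit$beta[1, 1]), tolerance = 1e-4)
      expect_equal(got$tau2, fit$sigma2, tolerance = 1e-4)
    }
  })
})

test_that("REML mean is equivariant to a common rescale of SEs and is
           GLS when tau2 is zero", {
  y <- c(0.05, 0.07, 0.06)
  s <- c(0.01, 0.015, 0.012)
  R <- matrix(0.3, 3, 3); diag(R) <- 1
  base <- reml_meta_dmr_effect(y, s, R)
  # consistent rescale of the error structure leaves the mean unchanged
  big <- reml_meta_dmr_effect(y, s * 3, R)
  expect_equal(big$beta_gp, oracle_gls_mean(y, s * 3, R)$estimate,
               tolerance = 1e-6)
  expect_equal(base$beta_gp,
               oracle_reml_grid(y, s, R, upper = 0.005)$mu, tolerance = 1e-6)
})

test_that("per-CpG clumps respect the r2 threshold and beta_GP covers
           the common planted effect", {
  # LD-free panel: the marginal mQTL slope then targets exactly the
  # planted per-SNP effect shared by every member CpG
  covered <- logical(0)
  for (seed in 31:34) {
  cfg <- quick_cfg(seed, n_panel = 1200, n_snp_per_region = 5,
                   cis_effect = 0.04, ld_decay = 0)
  panel <- simulate_reference_panel(cfg)
  mq <- panel_mqtls(panel)
  ld <- panel_ld(panel)
  tr <- panel$truth
  for (r in 1:2) {
    cpgs <- strsplit(tr$regions$cpgs[r], ",")[[1]]
    reg <- structure(list(exposure = "smoking", chrom = tr$regions$chrom[r],
                          start = tr$regions$start[r],
                          end = tr$regions$end[r], shared_cpgs = cpgs,
                          sentinel = cpgs[1]), class = "shared_region")
    fake <- mk_expo_ewas(cpgs, seq_along(cpgs), p = seq_along(cpgs) * 1e-5)
    cc <- residual_cor(panel$methylation, cpgs)
    inst <- build_instrument_set(reg, mq, ld, fake, cc)
    sel <- inst$selection
    for (k in unique(sel$step)) {
      snps <- sel$snp[sel$step == k]
      if (length(snps) > 1) {
        off <- ld[snps, snps]^2
        diag(off) <- 0
        expect_lt(max(off), 0.01)
      }
    }
    truth_eff <- tr$cis$effect[match(inst$snps$snp, tr$cis$snp)]
    covered <- c(covered,
                 abs(inst$snps$beta_gp - truth_eff) < 2 * inst$snps$se_gp)
  }
  }
  # binomial lower bound on nominal ~95% coverage over the pooled SNPs
  expect_gte(mean(covered), 0.85)
})

test_that("under strong LD the selected instrument is internally
           near-independent", {
  cfg <- quick_cfg(36, n_panel = 1500, n_snp_per_region = 8,
                   cis_effect = 0.04, ld_decay = 0.4)
  panel <- simulate_reference_panel(cfg)
  mq <- panel_mqtls(panel)
  ld <- panel_ld(panel)
  tr <- panel$truth
  cpgs <- strsplit(tr$regions$cpgs[1], ",")[[1]]
  reg <- structure(list(exposure = "smoking", chrom = tr$regions$chrom[1],
                        start = tr$regions$start[1], end = tr$regions$end[1],
                        shared_cpgs = cpgs, sentinel = cpgs[1]),
                   class = "shared_region")
  fake <- mk_expo_ewas(cpgs, seq_along(cpgs), p = seq_along(cpgs) * 1e-5)
  sel <- build_instrument(reg, mq, ld, fake)
  expect_gt(nrow(sel), 0)
  for (k in unique(sel$step)) {
    snps <- sel$snp[sel$step == k]
    if (length(snps) > 1) {
      off <- ld[snps, snps]^2
      diag(off) <- 0
      expect_lt(max(off), 0.01)
    }
  }
})
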