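test_that("Wald ratio has its closed forms and delta-method SE", {
  # null outcome effect: HR exactly 1
  w0 <- wald_ratio(0, 0.02, 0.5, 0.05)
  expect_identical(w0$beta, 0)
  expect_identical(w0$hr, 1)
  # exact instrument: estimate and SE pass through
  w1 <- wald_ratio(0.1, 0.02, 1, 0)
  expect_equal(w1$beta, 0.1)
  expect_equal(w1$se, 0.02)
  # worked example: se = sqrt(0.0016 + 0.0004)
  w2 <- wald_ratio(0.1, 0.02, 0.5, 0.05)
  expect_equal(w2$beta, 0.2, tolerance = 1e-12)
  expect_equal(w2$se, sqrt(0.02^2 / 0.25 + 0.01 * 0.05^2 / 0.0625),
               tolerance = 1e-12)
  expect_error(wald_ratio(0.1, 0.02, 0, 0.05), "zero")
})

test_that("delta-method SE agrees with Monte-Carlo error propagation", {
  mc <- with_seed(101, {
    gd <- rnorm(1e6, 0.1, 0.02)
    gp <- rnorm(1e6, 0.5, 0.05)
    sd(gd / gp)
  })
  expect_lt(abs(wald_ratio(0.1, 0.02, 0.5, 0.05)$se - mc) / mc, 0.02)
})

test_that("single-SNP IVW is the Wald ratio with first-order SE", {
  iv <- ivw_correlated(0.12, 0.03, 0.4, 0.02)
  wd <- wald_ratio(0.12, 0.03, 0.4, 0.02, order = 1)
  expect_equal(iv$beta, wd$beta, tolerance = 1e-12)
  expect_equal(iv$se, wd$se, tolerance = 1e-12)
})

test_that("IVW with identity correlation is textbook fixed-effect IVW
           of Wald ratios", {
  with_seed(102, {
    for (i in 1:20) {
      k <- sample(2:6, 1)
      bgp <- runif(k, 0.2, 0.8) * sample(c(-1, 1), k, replace = TRUE)
      bgd <- rnorm(k, 0.05, 0.05)
      segd <- runif(k, 0.02, 0.1)
      got <- ivw_correlated(bgd, segd, bgp, rep(0.01, k))
      ratios <- bgd / bgp
      w <- bgp^2 / segd^2   # first-order inverse-variance weights
      expect_equal(got$beta, sum(w * ratios) / sum(w), tolerance = 1e-10)
      expect_equal(got$se, sqrt(1 / sum(w)), tolerance = 1e-10)
    }
  })
  # two SNPs with equal seGD and equal bGP: the plain mean of the ratios
  got <- ivw_correlated(c(0.1, 0.2), c(0.05, 0.05), c(0.5, 0.5),
                        c(0.01, 0.01))
  expect_equal(got$beta, mean(c(0.1, 0.2) / 0.5), tolerance = 1e-12)
})

test_that("correlated IVW and Egger match naive GLS on random instances", {
  with_seed(103, {
    for (i in 1:20) {
      k <- sample(3:6, 1)
      bgp <- runif(k, 0.2, 0.8) * sample(c(-1, 1), k, replace = TRUE)
      bgd <- rnorm(k, 0.05, 0.05)
      segd <- runif(k, 0.02, 0.1)
      segp <- runif(k, 0.01, 0.03)
      A <- matrix(rnorm(k * k, 0, 0.3), k, k)
      rho <- cov2cor(crossprod(A) + diag(k))
      iv <- ivw_correlated(bgd, segd, bgp, segp, rho)
      want <- oracle_ivw(bgd, segd, bgp, rho)
      expect_equal(iv$beta, want$beta, tolerance = 1e-10)
      expect_equal(iv$se, want$se, tolerance = 1e-10)
      eg <- egger_correlated(bgd, segd, bgp, segp, rho)
      weg <- oracle_egger(bgd, segd, bgp, rho)
      expect_equal(eg$beta, weg$slope, tolerance = 1e-10)
      expect_equal(eg$se, weg$se_slope, tolerance = 1e-10)
      expect_equal(eg$intercept, weg$intercept, tolerance = 1e-10)
      expect_equal(eg$intercept_se, weg$se_intercept, tolerance = 1e-10)
    }
  })
})

test_that("Egger with the intercept pinned at zero reduces to IVW", {
  with_seed(104, {
    k <- 4
    bgp <- runif(k, 0.2, 0.8)
    bgd <- rnorm(k, 0.05, 0.05)
    segd <- runif(k, 0.02, 0.1)
    rho <- diag(k)
  })
  eg0 <- egger_correlated(bgd, segd, bgp, rep(0.01, k), rho,
                          intercept_zero = TRUE)
  iv <- ivw_correlated(bgd, segd, bgp, rep(0.01, k), rho)
  expect_equal(eg0$beta, iv$beta, tolerance = 1e-12)
  expect_equal(eg0$se, iv$se, tolerance = 1e-12)
  expect_error(egger_correlated(bgd[1:2], segd[1:2], bgp[1:2],
                                rep(0.01, 2), diag(2)), ">= 3")
})

test_that("MR estimates are scale-equivariant and allele-flip invariant", {
  with_seed(105, {
    k <- 5
    bgp <- runif(k, 0.2, 0.8)
    bgd <- rnorm(k, 0.05, 0.05)
    segd <- runif(k, 0.02, 0.1)
    segp <- runif(k, 0.01, 0.03)
    A <- matrix(rnorm(k * k, 0, 0.3), k, k)
    rho <- cov2cor(crossprod(A) + diag(k))
  })
  base <- ivw_correlated(bgd, segd, bgp, segp, rho)
  for (c0 in c(2, -0.5)) {
    sc <- ivw_correlated(bgd, segd, c0 * bgp, abs(c0) * segp, rho)
    expect_equal(sc$beta, base$beta / c0, tolerance = 1e-12)
    expect_equal(sc$se, base$se / abs(c0), tolerance = 1e-12)
  }
  # flipping one SNP's alleles negates bGP and bGD jointly, and the
  # corresponding row/column of the signed LD matrix
  flip <- c(-1, 1, 1, -1, 1)
  rho_f <- rho * outer(flip, flip)
  fl <- ivw_correlated(bgd * flip, segd, bgp * flip, segp, rho_f)
  expect_equal(fl$beta, base$beta, tolerance = 1e-12)
  expect_equal(fl$se, base$se, tolerance = 1e-12)
  eg <- egger_correlated(bgd, segd, bgp, segp, rho)
  eg_f <- egger_correlated(bgd * flip, segd, bgp * flip, segp, rho_f)
  expect_equal(eg_f$beta, eg$beta, tolerance = 1e-12)
  expect_equal(eg_f$intercept, eg$intercept, tolerance = 1e-12)
})

test_that("the Egger intercept detects planted directional pleiotropy
           and covers zero without it", {
  res <- t(vapply(1:500, function(s) {
    with_seed(2000 + s, {
      k <- 20
      bgp_true <- runif(k, 0.5, 1.5)
      segd <- rep(0.05, k)
      bgd0 <- rnorm(k, 0.1 * bgp_true, segd)             # no pleiotropy
      bgd1 <- rnorm(k, 0.1 * bgp_true + 0.05, segd)      # +0.05 on all
    })
    e0 <- egger_correlated(bgd0, segd, bgp_true, rep(0.01, k))
    e1 <- egger_correlated(bgd1, segd, bgp_true, rep(0.01, k))
    c(cover0 = abs(e0$intercept) < 1.959964 * e0$intercept_se,
      int1 = e1$intercept, se1 = e1$intercept_se)
  }, numeric(3)))
  expect_gt(mean(res[, "cover0"]), 0.92)
  expect_lt(mean(res[, "cover0"]), 0.98)
  expect_lt(abs(mean(res[, "int1"]) - 0.05), 2 * mean(res[, "se1"]))
})

test_that("harmonisation flips, drops and logs as required", {
  inst <- data.frame(
    snp = c("s1", "s2", "s3", "s4", "s5"),
    effect_allele = c("A", "A", "A", "A", "A"),
    other_allele = c("G", "G", "G", "G", "T"),
    eaf = c(0.3, 0.3, 0.3, 0.3, 0.45),
    beta_gp = 0.1, se_gp = 0.01, tau2 = 0, n_cpg = 2L, cpg_trail = "c1,c2",
    sentinel_beta = 0.1, sentinel_se = 0.01, stringsAsFactors = FALSE)
  outc <- data.frame(
    snp = c("s1", "s2", "s3", "s5"),
    effect_allele = c("A", "G", "C", "A"),
    loghr = c(0.2, 0.2, 0.2, 0.2), se = 0.1, p = 0.05, n_events = 100L,
    status = c("ok", "ok", "ok", "ok"), stringsAsFactors = FALSE)
  h <- harmonise_mr_input(inst, outc)
  acts <- setNames(h$log$action, h$log$snp)
  expect_identical(acts[["s1"]], "kept")
  expect_identical(acts[["s2"]], "flipped")
  expect_identical(acts[["s3"]], "incompatible_alleles")
  expect_identical(acts[["s4"]], "missing_outcome")
  expect_identical(acts[["s5"]], "palindromic_dropped")
  expect_identical(h$data$snp, c("s1", "s2"))
  expect_equal(h$data$loghr, c(0.2, -0.2))
})

test_that("mr_power has its boundary behaviour and matches an
           instrumented-regression simulation", {
  expect_equal(mr_power(409, 0.2, 1, 0.05)$power, 0.05, tolerance = 1e-12)
  expect_gt(mr_power(1e6, 0.5, 1.5, 0.05)$power, 0.9999)
  # closed form cross-check
  got <- mr_power(409, 0.2, 1.5, 0.05)$power
  z <- qnorm(0.975)
  ncp <- sqrt(409 * 0.2) * log(1.5)
  expect_equal(got, pnorm(ncp - z) + pnorm(-ncp - z), tolerance = 1e-6)
  # simulation oracle: score test of the reduced-form regression with
  # unit-variance exposure and outcome
  rej <- with_seed(106, {
    mean(vapply(1:1000, function(i) {
      n <- 409; r2 <- 0.2; b <- log(1.5)
      g <- rnorm(n)
      x <- sqrt(r2) * g + sqrt(1 - r2) * rnorm(n)
      y <- b * x + sqrt(max(1e-6, 1 - b^2)) * rnorm(n)
      summary(lm(y ~ g))$coefficients[2, 4] < 0.05
    }, logical(1)))
  })
  expect_lt(abs(got - rej), 0.03)
})

test_that("mr_region runs full and sentinel layouts and skips
           unharmonisable instruments", {
  reg <- structure(list(exposure = "smoking", chrom = "chr1", start = 100L,
                        end = 200L, shared_cpgs = c("c1", "c2"),
                        sentinel = "c1"), class = "shared_region")
  snps <- data.frame(
    snp = c("s1", "s2", "s3"), effect_allele = "A", other_allele = "G",
    eaf = 0.3, beta_gp = c(0.4, 0.5, 0.45), se_gp = 0.02, tau2 = 0,
    n_cpg = 2L, cpg_trail = "c1,c2",
    sentinel_beta = c(0.4, NA, 0.45), sentinel_se = c(0.02, NA, 0.02),
    stringsAsFactors = FALSE)
  inst <- structure(list(region = reg, sentinel = "c1", snps = snps,
                         mqtls = NULL, selection = NULL),
                    class = "instrument_set")
  outc <- data.frame(snp = c("s1", "s2", "s3"), effect_allele = "A",
                     loghr = c(0.1, 0.12, 0.09), se = 0.05, p = 0.03,
                     n_events = 100L, status = "ok",
                     stringsAsFactors = FALSE)
  ld <- diag(3); dimnames(ld) <- list(snps$snp, snps$snp)
  out <- mr_region(inst, outc, ld)
  expect_setequal(out$method[out$analysis == "all_dmr_cpgs"],
                  c("ivw", "egger"))
  # sentinel layout restricted to the two sentinel-proxying SNPs
  expect_identical(out$n_snp[out$analysis == "sentinel_only"], 2L)

  # single-SNP instrument: one Wald row for both layouts
  inst1 <- inst
  inst1$snps <- snps[1, , drop = FALSE]
  out1 <- mr_region(inst1, outc, ld)
  expect_identical(out1$method, c("wald", "wald"))
  expect_setequal(out1$analysis, c("all_dmr_cpgs", "sentinel_only"))

  # nothing harmonisable: flagged skip
  outc_bad <- outc
  outc_bad$effect_allele <- "C"
  out_bad <- mr_region(inst, outc_bad, ld)
  expect_identical(nrow(out_bad), 0L)
  expect_true(isTRUE(attr(out_bad, "skipped")))
  expect_true(all(attr(out_bad, "harmonisation")$action ==
                    "incompatible_alleles"))
})
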