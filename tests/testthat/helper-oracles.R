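# Independent brute-force oracles.  These deliberately use naive matrix
# algebra (explicit solve(), grid search, enumeration) so they share no
# code path with the package implementations they check.

oracle_gls_mean <- function(b, s, R) {
  V <- diag(s, length(s)) %*% R %*% diag(s, length(s))
  Vi <- solve(V)
  ones <- rep(1, length(b))
  denom <- drop(t(ones) %*% Vi %*% ones)
  est <- drop(t(ones) %*% Vi %*% b) / denom
  se <- denom^(-0.5)
  list(estimate = est, se = se, p = 2 * pnorm(-abs(est / se)))
}

oracle_ivw <- function(bgd, segd, bgp, rho) {
  Om <- diag(segd, length(segd)) %*% rho %*% diag(segd, length(segd))
  Oi <- solve(Om)
  xtox <- drop(t(bgp) %*% Oi %*% bgp)
  list(beta = drop(t(bgp) %*% Oi %*% bgd) / xtox, se = xtox^(-0.5))
}

oracle_egger <- function(bgd, segd, bgp, rho) {
  flip <- ifelse(bgp < 0, -1, 1)
  x <- bgp * flip
  y <- bgd * flip
  rho2 <- rho * outer(flip, flip)
  Om <- diag(segd, length(segd)) %*% rho2 %*% diag(segd, length(segd))
  Oi <- solve(Om)
  X <- cbind(1, x)
  covm <- solve(t(X) %*% Oi %*% X)
  coefs <- covm %*% t(X) %*% Oi %*% y
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = sqrt(covm[1, 1]), se_slope = sqrt(covm[2, 2]))
}

# REML by grid search over tau2: a coarse pass at `step`, then a local
# refinement around the best grid point so the quantisation of tau2 does
# not leak into mu at the comparison tolerance.
oracle_reml_grid <- function(y, se, R, upper = NULL, step = 1e-6) {
  k <- length(y)
  V <- diag(se, k) %*% R %*% diag(se, k)
  if (is.null(upper)) upper <- max(10 * var(y), 10 * max(se)^2)
  ones <- rep(1, k)
  ll_at <- function(t2) {
    S <- V + diag(t2, k)
    Si <- solve(S)
    s11 <- drop(t(ones) %*% Si %*% ones)
    mu <- drop(t(ones) %*% Si %*% y) / s11
    r <- y - mu
    -0.5 * (determinant(S)$modulus + log(s11) + drop(t(r) %*% Si %*% r))
  }
  grid <- seq(0, upper, by = step)
  ll <- vapply(grid, ll_at, numeric(1))
  t2 <- grid[which.max(ll)]
  fine <- seq(max(0, t2 - step), t2 + step, by = step / 1000)
  llf <- vapply(fine, ll_at, numeric(1))
  t2 <- fine[which.max(llf)]
  S <- V + diag(t2, k)
  Si <- solve(S)
  s11 <- drop(t(ones) %*% Si %*% ones)
  list(tau2 = t2, mu = drop(t(ones) %*% Si %*% y) / s11, se = s11^(-0.5))
}

# Exhaustive DMR caller for tiny inputs: enumerates candidates and all
# sub-windows directly from first principles.
oracle_call_dmrs <- function(ewas, M, p_enter = 0.05, max_gap = 500,
                             alpha = 0.05) {
  ew <- ewas[order(ewas$chrom, ewas$pos), ]
  qual <- ew$p < p_enter & ew$status == "ok"
  # candidates: brute-force over all contiguous index ranges, keeping
  # maximal qualifying runs
  n <- nrow(ew)
  is_run <- function(i, j) {
    if (any(!qual[i:j])) return(FALSE)
    if (length(unique(ew$chrom[i:j])) > 1) return(FALSE)
    if (length(unique(sign(ew$estimate[i:j]))) > 1) return(FALSE)
    if (j > i && any(diff(ew$pos[i:j]) > max_gap)) return(FALSE)
    TRUE
  }
  cands <- list()
  for (i in 1:n) for (j in i:n) {
    if (!is_run(i, j)) next
    left_ok <- i == 1 || !is_run(i - 1, j)
    right_ok <- j == n || !is_run(i, j + 1)
    if (left_ok && right_ok && j > i) cands[[length(cands) + 1]] <- i:j
  }
  # Sidak universe: all gap-eligible windows regardless of p
  elig <- 0
  for (i in 1:n) for (j in i:n) {
    if (j == i) next
    if (length(unique(ew$chrom[i:j])) > 1) next
    if (any(diff(ew$pos[i:j]) > max_gap)) next
    elig <- elig + 1
  }
  rows <- lapply(cands, function(idx) {
    cpgs <- ew$cpg[idx]
    R <- residual_cor(M, cpgs)
    best <- NULL
    for (a in seq_along(idx)) for (b in seq_along(idx)) {
      if (b <= a) next
      sub <- cpgs[a:b]
      o <- oracle_gls_mean(ew$estimate[match(sub, ew$cpg)],
                           ew$se[match(sub, ew$cpg)],
                           R[sub, sub, drop = FALSE])
      if (is.null(best) || o$p < best$p)
        best <- data.frame(cpgs = paste(sub, collapse = ","),
                           estimate = o$estimate, se = o$se, p = o$p)
    }
    best
  })
  out <- do.call(rbind, rows)
  if (!is.null(out)) {
    # same Sidak formula, evaluated in log space to survive tiny p
    out$p_adj <- pmin(1, -expm1(max(1, elig) * log1p(-out$p)))
    out <- out[order(out$p), ]
    rownames(out) <- NULL
  }
  list(table = out, n_windows = elig)
}

# Small simulation config used across tests.
quick_cfg <- function(seed, ...) {
  args <- list(...)
  defaults <- list(n_panel = 400, n_cohort = 300, n_cpg = 60, n_region = 2,
                   n_cpg_per_region = 4, n_snp_per_region = 4, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Zeroed exposure/mediation config for null simulations.
null_cfg <- function(seed, ...) {
  quick_cfg(seed,
            exposure_effects = list(smoking = c(0, 0), alcohol = c(0, 0),
                                    hpv = c(0, 0)),
            mediation_loghr = c(0, 0),
            direct_loghr = c(smoking = 0, alcohol = 0, hpv = 0), ...)
}

# A minimal methylation_matrix with iid noise around 0.5.
noise_methylation <- function(n, p, seed = 1, prefix = "cg") {
  with_seed(seed, {
    beta <- matrix(plogis(rnorm(n * p, 0, 0.3)), n, p)
    colnames(beta) <- sprintf("%s%05d", prefix, seq_len(p))
    rownames(beta) <- sprintf("s%04d", seq_len(n))
    anno <- data.frame(cpg = colnames(beta), chrom = "chr1",
                       pos = seq_len(p) * 1000L)
    methylation_matrix(beta, anno)
  })
}
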