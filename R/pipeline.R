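# End-to-end orchestration: simulate -> SVA -> EWAS -> DMR -> overlap ->
# instruments -> SNP survival GWAS -> MR, with a run manifest recording
# seeds, thresholds, checksums and counts.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the synthetic panel and cohort.
#' @param p_enter,max_gap DMR candidate parameters.
#' @param maf_min,p_max,r2_max Instrument filters and clump threshold.
#' @param alpha_dmr Sidak significance level for DMR calls.
#' @param n_perm_sva Permutations for surrogate-variable selection.
#' @param out_dir Output directory for stage tables and the manifest.
#' @param stages Character vector of stages to run (prefix of the full
#'   chain; later stages depend on earlier ones).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), p_enter = 0.05,
                            max_gap = 500, maf_min = 0.05, p_max = 5e-8,
                            r2_max = 0.01, alpha_dmr = 0.05,
                            n_perm_sva = 25, out_dir = tempfile("ewasmr_run_"),
                            stages = c("simulate", "ewas", "dmr", "overlap",
                                       "snp_survival", "mr")) {
  stopifnot(inherits(sim, "sim_config"),
            p_enter > 0, p_enter < 1, max_gap >= 0,
            maf_min >= 0, maf_min < 0.5, p_max > 0, p_max < 1,
            r2_max > 0, r2_max <= 1, alpha_dmr > 0, alpha_dmr < 1)
  structure(list(sim = sim, p_enter = p_enter, max_gap = max_gap,
                 maf_min = maf_min, p_max = p_max, r2_max = r2_max,
                 alpha_dmr = alpha_dmr, n_perm_sva = n_perm_sva,
                 out_dir = out_dir, stages = stages),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg[setdiff(names(cfg), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the stages in dependency order, writing every stage table to
#' `cfg$out_dir` and a JSON run manifest (`manifest.json`) with the
#' config hash, seed, per-file checksums, the thresholds actually
#' applied, and stage counts.  Any stage failure halts the downstream
#' stages; the manifest is written regardless and records the failure
#' point.  A rerun with an identical config reproduces identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly, as a list; the in-memory stage
#'   results are attached as attribute `results`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- list(config_hash = config_hash(cfg), seed = cfg$sim$seed,
              thresholds = list(p_enter = cfg$p_enter, max_gap = cfg$max_gap,
                                maf_min = cfg$maf_min, p_max = cfg$p_max,
                                r2_max = cfg$r2_max,
                                alpha_dmr = cfg$alpha_dmr,
                                bonferroni = as.numeric(bonferroni_threshold(0.05, 862491)),
                                suggestive = suggestive_threshold()),
              stages = list(), counts = list(), files = list(),
              failure = NULL)
  res <- list()
  fail <- function(stage, msg) {
    man$failure <<- list(stage = stage, message = msg)
  }
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    man$files[[name]] <<- unname(tools::md5sum(path))
  }
  run_stage <- function(name, body) {
    if (!is.null(man$failure) || !(name %in% cfg$stages)) return(invisible())
    ok <- tryCatch({ body(); TRUE },
                   error = function(e) { fail(name, conditionMessage(e)); FALSE })
    man$stages[[name]] <<- if (ok) "ok" else "failed"
    invisible()
  }

  run_stage("simulate", function() {
    res$panel <<- simulate_reference_panel(cfg$sim)
    res$cohort <<- simulate_clinical_cohort(cfg$sim, res$panel$truth)
    ph <- res$cohort$phenotypes
    ph$survival_days <- res$cohort$survival_days
    ph$event <- res$cohort$event
    man$counts$event_fraction <<- attr(res$cohort, "event_fraction")
    man$counts$n_cpg <<- ncol(res$cohort$methylation$beta)
    emit("phenotypes.tsv", function(p) write_stage_table(ph, p, "phenotype"))
    emit("methylation.tsv", function(p)
      write_matrix_tsv(res$cohort$methylation$beta, p, c(0, 1)))
    emit("dosage.tsv", function(p)
      write_matrix_tsv(res$cohort$dosage, p, c(0, 2)))
    emit("truth_regions.tsv", function(p)
      write_stage_table(res$panel$truth$regions, p, "truth_region"))
  })

  run_stage("ewas", function() {
    co <- res$cohort
    ph <- co$phenotypes
    base_cov <- cbind(age = ph$age, sex = ph$sex)
    expo <- cbind(smoking = ph$smoking, alcohol_units = ph$alcohol_units,
                  hpv = ph$hpv)
    # protect the variables of interest: the SV model includes them, so
    # the surrogate variables live in the residual space
    res$svs <<- estimate_surrogate_variables(
      co$methylation, cbind(base_cov, expo), n_perm = cfg$n_perm_sva,
      seed = cfg$sim$seed + 10L)
    man$counts$n_sv <<- res$svs$K
    res$ewas <<- list(
      smoking = run_linear_ewas(co$methylation, ph$smoking,
        cbind(base_cov, expo[, c("alcohol_units", "hpv")]), res$svs),
      alcohol = run_linear_ewas(co$methylation, ph$alcohol_units,
        cbind(base_cov, expo[, c("smoking", "hpv")]), res$svs),
      hpv = run_linear_ewas(co$methylation, ph$hpv,
        cbind(base_cov, expo[, c("smoking", "alcohol_units")]), res$svs),
      survival_m1 = run_cox_ewas(co$methylation, co$survival_days,
        co$event, base_cov, res$svs, model = 1),
      survival_m2 = run_cox_ewas(co$methylation, co$survival_days,
        co$event, base_cov, res$svs, model = 2, exposures = ph))
    for (nm in names(res$ewas))
      emit(sprintf("ewas_%s.tsv", nm), local({
        t <- res$ewas[[nm]]
        function(p) write_stage_table(t, p, "ewas")
      }))
  })

  run_stage("dmr", function() {
    co <- res$cohort
    ph <- co$phenotypes
    cov <- cbind(age = ph$age, sex = ph$sex, smoking = ph$smoking,
                 alcohol_units = ph$alcohol_units, hpv = ph$hpv,
                 res$svs$sv)
    res$dmrs <<- lapply(res$ewas, function(ew)
      call_dmrs(ew, co$methylation, cov, cfg$p_enter, cfg$max_gap,
                cfg$alpha_dmr))
    man$counts$n_dmr <<- vapply(res$dmrs, function(d) sum(d$significant),
                                integer(1))
    for (nm in names(res$dmrs))
      emit(sprintf("dmr_%s.tsv", nm), local({
        t <- res$dmrs[[nm]]
        function(p) write_stage_table(t, p, "dmr")
      }))
  })

  run_stage("overlap", function() {
    shared <- list()
    for (e in c("smoking", "alcohol", "hpv")) {
      sh <- overlap_dmrs(res$dmrs[[e]], res$dmrs$survival_m1,
                         res$ewas[[e]], exposure = e, alpha = cfg$alpha_dmr)
      shared <- c(shared, sh)
    }
    res$shared <<- shared
    man$counts$n_shared_regions <<- length(shared)
    man$counts$n_shared_cpgs <<- sum(vapply(shared, function(s)
      length(s$shared_cpgs), integer(1)))

    res$mqtls <<- panel_mqtls(res$panel)
    res$ld <<- panel_ld(res$panel)
    emit("mqtls.tsv", function(p) write_stage_table(res$mqtls, p, "mqtl"))
    emit("ld.tsv", function(p) write_ld_tsv(res$ld, p))

    res$instruments <<- lapply(seq_along(shared), function(i) {
      s <- shared[[i]]
      cc <- residual_cor(res$panel$methylation, s$shared_cpgs)
      build_instrument_set(s, res$mqtls, res$ld, res$ewas[[s$exposure]],
                           cc, cfg$maf_min, cfg$p_max, cfg$r2_max)
    })
    inst_tab <- do.call(rbind, lapply(seq_along(res$instruments), function(i) {
      sn <- res$instruments[[i]]$snps
      if (nrow(sn) == 0) return(NULL)
      s <- res$instruments[[i]]$region
      cbind(data.frame(region = sprintf("%s:%d-%d", s$chrom, s$start, s$end),
                       stringsAsFactors = FALSE), sn)
    }))
    if (is.null(inst_tab))
      inst_tab <- data.frame(region = character(), snp = character(),
                             beta_gp = numeric(), se_gp = numeric(),
                             tau2 = numeric(), n_cpg = integer(),
                             cpg_trail = character(), stringsAsFactors = FALSE)
    man$counts$n_instrument_snps <<- nrow(inst_tab)
    emit("instruments.tsv", function(p)
      write_stage_table(inst_tab, p, "instrument"))
  })

  run_stage("snp_survival", function() {
    snp_ids <- unique(unlist(lapply(res$instruments, function(x) x$snps$snp)))
    co <- res$cohort
    if (length(snp_ids) == 0) {
      res$snp_survival <<- run_snp_survival_gwas(
        co$dosage[, 0, drop = FALSE][, 0, drop = FALSE],
        co$survival_days, co$event, co$phenotypes$age,
        co$phenotypes$sex)[0, ]
    } else {
      res$snp_survival <<- run_snp_survival_gwas(
        co$dosage[, snp_ids, drop = FALSE], co$survival_days, co$event,
        co$phenotypes$age, co$phenotypes$sex)
    }
    emit("snp_survival.tsv", function(p)
      write_stage_table(res$snp_survival, p, "snp_survival"))
  })

  run_stage("mr", function() {
    mr_tab <- do.call(rbind, lapply(res$instruments, function(inst) {
      if (isTRUE(attr(inst, "skipped"))) return(NULL)
      mr_region(inst, res$snp_survival, res$ld)
    }))
    if (is.null(mr_tab))
      mr_tab <- cbind(data.frame(region = character(), analysis = character(),
                                 stringsAsFactors = FALSE),
                      mr_estimate_row("ivw", 1L, 0, 1)[0, ])
    res$mr <<- mr_tab
    man$counts$n_mr_rows <<- nrow(mr_tab)
    emit("mr.tsv", function(p) write_stage_table(mr_tab, p, "mr"))
  })

  man_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(structure(man, results = res))
}
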