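# Interchange formats: tab-delimited, UTF-8, Unix newlines, "." for
# missing, numerics serialised at 17 significant digits so that
# write -> read -> write round-trips byte-identically.

STAGE_SCHEMAS <- list(
  ewas = list(cols = c("cpg", "chrom", "pos", "estimate", "se", "p", "n",
                       "status"),
              types = c("c", "c", "i", "n", "n", "n", "i", "c")),
  snp_survival = list(cols = c("snp", "effect_allele", "loghr", "se", "p",
                               "n_events", "status"),
                      types = c("c", "c", "n", "n", "n", "i", "c")),
  dmr = list(cols = c("chrom", "start", "end", "n_cpg", "cpgs", "estimate",
                      "se", "p", "p_adj"),
             types = c("c", "i", "i", "i", "c", "n", "n", "n", "n")),
  mqtl = list(cols = c("snp", "cpg", "effect_allele", "other_allele", "eaf",
                       "beta", "se", "p"),
              types = c("c", "c", "c", "c", "n", "n", "n", "n")),
  instrument = list(cols = c("region", "snp", "beta_gp", "se_gp", "tau2",
                             "n_cpg", "cpg_trail"),
                    types = c("c", "c", "n", "n", "n", "i", "c")),
  mr = list(cols = c("region", "analysis", "method", "n_snp", "beta", "se",
                     "hr", "ci_low", "ci_high", "p", "intercept",
                     "intercept_se", "intercept_p"),
            types = c("c", "c", "c", "i", "n", "n", "n", "n", "n", "n",
                      "n", "n", "n")),
  phenotype = list(cols = c("sample_id", "smoking", "alcohol_units", "hpv",
                            "age", "sex", "batch", "survival_days",
                            "event"),
                   types = c("c", "i", "n", "i", "n", "i", "i", "n", "i")),
  truth_region = list(cols = c("region", "chrom", "start", "end", "n_cpg",
                               "intercept", "eff_smoking", "eff_alcohol",
                               "eff_hpv", "mediation_loghr", "cpgs"),
                      types = c("i", "c", "i", "i", "i", "n", "n", "n",
                                "n", "n", "c"))
)

fmt_field <- function(x, type) {
  out <- switch(type,
    c = as.character(x),
    i = sprintf("%d", as.integer(x)),
    n = sprintf("%.17g", x))
  out[is.na(x)] <- "."
  out
}

parse_field <- function(x, type, path, col) {
  x[x == "."] <- NA
  out <- switch(type, c = x, i = suppressWarnings(as.integer(x)),
                n = suppressWarnings(as.numeric(x)))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad))
    stop(sprintf("%s: malformed value in column '%s' at data line %d",
                 path, col, bad[1]))
  out
}

#' Write and read pipeline interchange tables
#'
#' Every stage table travels as a fixed-schema TSV (see `STAGE_SCHEMAS`):
#' tab-delimited, `.` for missing, numerics at 17 significant digits so
#' a write/read/write cycle is byte-identical.  Malformed rows fail with
#' their line number.
#'
#' @param df Data frame holding at least the schema's columns.
#' @param path File path.
#' @param schema Schema name: one of `names(STAGE_SCHEMAS)`.
#' @return `read_stage_table` returns the typed data frame;
#'   `write_stage_table` returns `path` invisibly.
#' @export
write_stage_table <- function(df, path, schema) {
  sc <- STAGE_SCHEMAS[[schema]]
  if (is.null(sc)) stop(sprintf("unknown schema '%s'", schema))
  missing <- setdiff(sc$cols, names(df))
  if (length(missing))
    stop(sprintf("missing columns for schema '%s': %s", schema,
                 paste(missing, collapse = ", ")))
  cells <- mapply(function(col, type) fmt_field(df[[col]], type),
                  sc$cols, sc$types, SIMPLIFY = FALSE)
  body <- if (nrow(df) == 0) character(0) else do.call(paste, c(cells, sep = "\t"))
  writeLines(c(paste(sc$cols, collapse = "\t"), body), path, sep = "\n")
  invisible(path)
}

#' @rdname write_stage_table
#' @export
read_stage_table <- function(path, schema) {
  sc <- STAGE_SCHEMAS[[schema]]
  if (is.null(sc)) stop(sprintf("unknown schema '%s'", schema))
  lines <- readLines(path)
  if (length(lines) == 0) stop(sprintf("%s: empty file", path))
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, sc$cols))
    stop(sprintf("%s: header does not match schema '%s'", path, schema))
  body <- lines[-1]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(sc$cols))
  if (length(bad))
    stop(sprintf("%s: wrong field count at data line %d", path, bad[1]))
  cols <- lapply(seq_along(sc$cols), function(k) {
    vals <- vapply(parts, `[[`, character(1), k)
    parse_field(vals, sc$types[k], path, sc$cols[k])
  })
  names(cols) <- sc$cols
  as.data.frame(cols, stringsAsFactors = FALSE)
}

#' Write and read sample-by-feature numeric matrices
#'
#' Methylation beta and genotype dosage matrices travel as TSVs with a
#' leading `sample_id` column and one column per feature.  Values outside
#' the declared range fail at read with the offending line number.
#'
#' @param mat Numeric matrix with row and column names.
#' @param path File path.
#' @param range Permitted closed interval, e.g. `c(0, 1)` for beta values
#'   and `c(0, 2)` for dosages; NULL to skip the check.
#' @return `read_matrix_tsv` returns the matrix; the writer returns
#'   `path` invisibly.
#' @export
write_matrix_tsv <- function(mat, path, range = NULL) {
  if (!is.null(range) && any(mat < range[1] | mat > range[2]))
    stop(sprintf("values outside [%g, %g]", range[1], range[2]))
  header <- paste(c("sample_id", colnames(mat)), collapse = "\t")
  rows <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rownames(mat)[i], sprintf("%.17g", mat[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path, sep = "\n")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, range = NULL) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  feats <- header[-1]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  n <- length(parts)
  out <- matrix(NA_real_, n, length(feats),
                dimnames = list(character(n), feats))
  ids <- character(n)
  for (i in seq_len(n)) {
    row <- parts[[i]]
    if (length(row) != length(header))
      stop(sprintf("%s: wrong field count at data line %d", path, i))
    vals <- suppressWarnings(as.numeric(row[-1]))
    if (anyNA(vals))
      stop(sprintf("%s: malformed numeric at data line %d", path, i))
    if (!is.null(range) && any(vals < range[1] | vals > range[2]))
      stop(sprintf("%s: value outside [%g, %g] at data line %d",
                   path, range[1], range[2], i))
    ids[i] <- row[1]
    out[i, ] <- vals
  }
  rownames(out) <- ids
  out
}

#' Write an LD matrix as TSV with a SNP-id header
#'
#' @param ld Square correlation matrix with SNP-id dimnames.
#' @param path File path.
#' @export
write_ld_tsv <- function(ld, path) {
  header <- paste(c("snp", colnames(ld)), collapse = "\t")
  rows <- vapply(seq_len(nrow(ld)), function(i)
    paste(c(rownames(ld)[i], sprintf("%.17g", ld[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path, sep = "\n")
  invisible(path)
}

#' @rdname write_ld_tsv
#' @export
read_ld_tsv <- function(path) {
  m <- read_matrix_tsv(path, range = c(-1, 1))
  m
}

#' Export a DMR table as BED6
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open,
#' so `start` decrements by one and `end` is unchanged.
#'
#' @param dmrs A `dmr_table`.
#' @param path File path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  lines <- vapply(seq_len(nrow(dmrs)), function(i) {
    score <- min(1000L, as.integer(round(-10 * log10(max(dmrs$p_adj[i],
                                                         1e-100)))))
    paste(c(dmrs$chrom[i], sprintf("%d", dmrs$start[i] - 1L),
            sprintf("%d", dmrs$end[i]),
            sprintf("dmr_%d", i), sprintf("%d", max(0L, score)), "."),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
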