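# CT-lncRNA / EECT-lncRNA calling.
#
# A TS-lncRNA is a CT-lncRNA in a cancer type when it is expressed above the
# unit-dialect floor (RPKM > 0.1, or normalized read counts > 5) in at least
# 1% of samples. A CT-lncRNA is an EECT-lncRNA when its zero-ruled log2
# expression strictly exceeds mean + 3 SD of that cohort's values in at
# least 1% of samples. Both inequalities at the thresholds are strict; the
# 1% criterion is >= on the exact fraction.

#' log2 transform with the zero rule
#'
#' Expression values of zero are set to one before the log2 transform, so a
#' zero maps to 0 on log2 scale and the extreme-expression mean/SD are
#' computed over all samples.
#'
#' @param values non-negative numeric vector or matrix.
#' @return log2-transformed values.
#' @examples
#' log2_with_zero_rule(c(0, 1, 8)) # 0 0 3
#' @export
log2_with_zero_rule <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    ctl_stop("negative expression value in log2 transform", "domain_error")
  }
  values[values == 0] <- 1
  log2(values)
}

#' Call CT genes in one tumor cohort
#'
#' @param expr `expr_matrix` of one cancer type.
#' @param ts_genes character vector of testis-specific gene ids (the CT
#'   candidates).
#' @param floor expression floor; defaults to the unit dialect's floor
#'   (0.1 for RPKM, 5 for normalized read counts). Strict `>`.
#' @param min_frac minimum fraction of expressing samples (default 0.01,
#'   evaluated as `>=` on count / n_samples).
#' @return data.table with gene_id, is_ct, frac_expressed for every gene of
#'   the matrix (genes outside `ts_genes` are never CT).
#' @export
call_ct <- function(expr, ts_genes, floor = NULL, min_frac = 0.01) {
  assert_that(ncol(expr) >= 1, "empty tumor cohort", "config_error")
  floor <- floor %||% default_floor(expr_unit(expr))
  frac <- rowMeans(unclass(expr) > floor)
  data.table::data.table(
    gene_id = rownames(expr),
    is_ct = rownames(expr) %in% ts_genes & frac >= min_frac,
    frac_expressed = frac
  )
}

#' Call extremely highly expressed (EE) CT genes in one tumor cohort
#'
#' Per gene, the EE threshold is mean + `k_sd` x SD of the zero-ruled log2
#' values over all samples of the cohort (sample SD, n - 1 denominator); the
#' gene is EECT when strictly more than the threshold in at least `min_frac`
#' of samples.
#'
#' @param expr `expr_matrix` of one cancer type (>= 2 samples).
#' @param ct_genes character vector of CT gene ids.
#' @param k_sd number of SDs above the mean (default 3).
#' @param min_frac minimum fraction of extreme samples (default 0.01).
#' @return data.table with gene_id, is_ct, is_eect, ee_threshold, frac_ee.
#' @export
call_eect <- function(expr, ct_genes, k_sd = 3, min_frac = 0.01) {
  assert_that(ncol(expr) >= 2,
              "EE threshold undefined for a cohort of fewer than 2 samples",
              "config_error")
  lg <- log2_with_zero_rule(unclass(expr))
  mu <- rowMeans(lg)
  sd <- apply(lg, 1, stats::sd)
  thr <- mu + k_sd * sd
  frac_ee <- rowMeans(lg > thr)
  is_ct <- rownames(expr) %in% ct_genes
  data.table::data.table(
    gene_id = rownames(expr),
    is_ct = is_ct,
    is_eect = is_ct & frac_ee >= min_frac,
    ee_threshold = thr,
    frac_ee = frac_ee
  )
}

#' Full CT/EECT call table over several cancer types
#'
#' Runs [call_ct()] then [call_eect()] per cohort and binds the per-cancer
#' rows; EECT calls are restricted to that cohort's CT genes, so the
#' EECT-in-CT nesting holds per cancer type and in the union.
#'
#' @param cohorts named list of `expr_matrix`, one per cancer type.
#' @param ts_genes testis-specific candidate gene ids.
#' @param floor,min_frac,k_sd see [call_ct()] and [call_eect()].
#' @return a `ct_call_table` data.table with gene_id, cancer_type, is_ct,
#'   is_eect, ee_threshold, frac_expressed, frac_ee.
#' @export
ct_call_table <- function(cohorts, ts_genes, floor = NULL, min_frac = 0.01,
                          k_sd = 3) {
  rows <- lapply(names(cohorts), function(type) {
    ct <- call_ct(cohorts[[type]], ts_genes, floor = floor, min_frac = min_frac)
    ee <- call_eect(cohorts[[type]], ct$gene_id[ct$is_ct], k_sd = k_sd,
                    min_frac = min_frac)
    data.table::data.table(
      gene_id = ct$gene_id, cancer_type = type,
      is_ct = ct$is_ct, is_eect = ee$is_eect,
      ee_threshold = ee$ee_threshold,
      frac_expressed = ct$frac_expressed, frac_ee = ee$frac_ee
    )
  })
  out <- data.table::rbindlist(rows)
  data.table::setattr(out, "class", c("ct_call_table", class(out)))
  out
}

#' Per-sample activation counts of EECT genes
#'
#' For each sample, the number of EECT genes whose zero-ruled log2 value
#' strictly exceeds that gene's cohort EE threshold.
#'
#' @param expr `expr_matrix` of one cancer type.
#' @param eect_calls `call_eect()` output for the same cohort.
#' @return data.table with sample_id, n_activated_eect.
#' @export
activation_counts <- function(expr, eect_calls) {
  assert_that(all(eect_calls$gene_id %in% rownames(expr)),
              "EECT calls refer to genes absent from the cohort",
              "consistency_error")
  eect <- eect_calls[eect_calls$is_eect, ]
  if (nrow(eect) == 0) {
    return(data.table::data.table(sample_id = colnames(expr),
                                  n_activated_eect = 0L))
  }
  lg <- log2_with_zero_rule(unclass(expr)[eect$gene_id, , drop = FALSE])
  above <- lg > eect$ee_threshold      # thresholds recycle down columns
  data.table::data.table(
    sample_id = colnames(expr),
    n_activated_eect = as.integer(colSums(above))
  )
}

#' Per-sample activation matrix of EECT genes
#'
#' Boolean genes x samples matrix: sample's zero-ruled log2 value strictly
#' above the gene's cohort EE threshold. Input to the mutual-exclusivity
#' screen.
#'
#' @inheritParams activation_counts
#' @export
activation_matrix <- function(expr, eect_calls) {
  eect <- eect_calls[eect_calls$is_eect, ]
  if (nrow(eect) == 0) {
    return(matrix(FALSE, 0, ncol(expr), dimnames = list(NULL, colnames(expr))))
  }
  lg <- log2_with_zero_rule(unclass(expr)[eect$gene_id, , drop = FALSE])
  lg > eect$ee_threshold
}

#' Composition enrichment of a called gene set across strata
#'
#' Per stratum (biotype or chromosome), a two-sided Fisher's exact test of
#' (in stratum vs not) x (called vs background-only), with the enrichment
#' ratio observed/expected proportion and BH adjustment across strata.
#'
#' @param called character vector of called gene ids.
#' @param genes `gene_models` covering called and background genes.
#' @param background character vector of background gene ids (superset of
#'   the sensible universe; called genes are included in the universe
#'   whether or not they are listed).
#' @param stratifier "biotype" or "chromosome".
#' @return data.table with stratum, n_called_in, n_called, n_universe_in,
#'   n_universe, enrichment_ratio, p_raw, p_bh.
#' @export
composition_enrichment <- function(called, genes, background,
                                   stratifier = c("biotype", "chromosome")) {
  stratifier <- match.arg(stratifier)
  assert_that(length(background) > 0, "empty background gene set", "config_error")
  universe <- unique(c(called, background))
  g <- genes[genes$gene_id %in% universe, ]
  assert_that(all(called %in% g$gene_id),
              "every called gene needs a gene model", "config_error")
  strat <- if (stratifier == "biotype") g$biotype else g$chrom
  is_called <- g$gene_id %in% called
  res <- lapply(sort(unique(strat)), function(s) {
    a <- sum(is_called & strat == s)
    b <- sum(is_called & strat != s)
    c_ <- sum(!is_called & strat == s)
    d <- sum(!is_called & strat != s)
    ft <- fisher_exact_2x2(a, b, c_, d)
    expected <- sum(strat == s) / length(strat)
    observed <- a / max(1L, sum(is_called))
    data.table::data.table(
      stratum = s, n_called_in = a, n_called = sum(is_called),
      n_universe_in = sum(strat == s), n_universe = length(strat),
      enrichment_ratio = observed / expected, p_raw = ft$p.value
    )
  })
  out <- data.table::rbindlist(res)
  out$p_bh <- bh_adjust(out$p_raw)
  out
}
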