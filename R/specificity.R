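# Testis-specificity classification of lncRNAs from a multi-tissue normal
# panel, plus the lncRNA gene-model filtering rules (lncRNA biotypes only,
# no exon overlapping a coding gene on either strand).

#' Specificity measure (SPM) of a tissue expression profile
#'
#' \eqn{SPM = x_t^2 / \sum_i x_i^2} over per-tissue mean expression: 1 when
#' expression is confined to the target tissue, 1/k for a uniform profile
#' over k tissues. Scale-invariant and monotone in the target tissue's
#' expression.
#'
#' @param expr_by_tissue named non-negative vector of per-tissue mean
#'   expression.
#' @param target_tissue name of the target tissue (default "testis").
#' @return SPM in \[0, 1\].
#' @examples
#' compute_spm(c(testis = 10, liver = 0, lung = 0)) # 1
#' @export
compute_spm <- function(expr_by_tissue, target_tissue = "testis") {
  assert_that(target_tissue %in% names(expr_by_tissue),
              "target tissue '%s' absent from the expression profile",
              "config_error", target_tissue)
  assert_that(all(expr_by_tissue >= 0), "expression must be non-negative",
              "domain_error")
  tot <- sum(expr_by_tissue^2)
  if (tot == 0) {
    ctl_stop("specificity undefined for an all-zero expression profile",
             "domain_error")
  }
  unname(expr_by_tissue[target_tissue]^2 / tot)
}

#' Keep lncRNA gene models that do not overlap coding genes
#'
#' Retains genes whose biotype is one of the six lncRNA biotypes and none of
#' whose exons overlaps (by >= 1 bp, on either strand) the span of any
#' coding gene.
#'
#' @param genes `gene_models` candidates.
#' @param coding_genes `gene_models` of known coding genes.
#' @return filtered `gene_models`.
#' @export
filter_lncrna_models <- function(genes, coding_genes) {
  keep_bt <- genes$biotype %in% LNCRNA_BIOTYPES
  if (nrow(coding_genes) == 0 || !any(keep_bt)) {
    return(genes[keep_bt, ])
  }
  ex <- data.table::data.table(
    gene_idx = rep(seq_len(nrow(genes)), lengths(genes$exons_start)),
    chrom = rep(genes$chrom, lengths(genes$exons_start)),
    start = unlist(genes$exons_start),
    end = unlist(genes$exons_end)
  )
  exon_gr <- genes_to_granges(ex)
  cod_gr <- genes_to_granges(coding_genes)
  GenomicRanges::strand(exon_gr) <- "*"
  GenomicRanges::strand(cod_gr) <- "*"
  hits <- GenomicRanges::findOverlaps(exon_gr, cod_gr, minoverlap = 1L)
  bad <- unique(ex$gene_idx[S4Vectors::queryHits(hits)])
  keep <- keep_bt & !(seq_len(nrow(genes)) %in% bad)
  genes[keep, ]
}

#' Classify genes as testis-specific from a normal panel
#'
#' Computes per-tissue mean expression for every gene, the SPM toward
#' testis, and assigns categories by the configured cutoffs.
#'
#' @param panel `expr_matrix` of the normal panel.
#' @param tissue_labels data.frame mapping sample_id to tissue; every panel
#'   sample must be covered and "testis" must be present.
#' @param high,moderate SPM cutoffs for the TS_high_confidence and
#'   TS_moderate categories.
#' @return data.table with gene_id, spm_testis, category,
#'   passed_overlap_filter (all TRUE here; set by the caller when the gene
#'   models have been filtered).
#' @export
classify_testis_specific <- function(panel, tissue_labels,
                                     high = 0.9, moderate = 0.6) {
  tl <- data.table::as.data.table(tissue_labels)
  assert_that(all(colnames(panel) %in% tl$sample_id),
              "every panel sample needs a tissue label", "config_error")
  tissue <- tl$tissue[match(colnames(panel), tl$sample_id)]
  assert_that("testis" %in% tissue,
              "no testis samples in the panel", "config_error")
  assert_that(high >= moderate,
              "high-confidence SPM cutoff must be >= the moderate cutoff",
              "config_error")
  tissues <- unique(tissue)
  means <- vapply(tissues, function(t)
    rowMeans(unclass(panel)[, tissue == t, drop = FALSE]),
    numeric(nrow(panel)))
  spm <- vapply(seq_len(nrow(panel)), function(i) {
    v <- means[i, ]
    if (sum(v^2) == 0) return(NA_real_)
    compute_spm(v, "testis")
  }, numeric(1))
  category <- ifelse(is.na(spm), "non_TS",
                     ifelse(spm >= high, "TS_high_confidence",
                            ifelse(spm >= moderate, "TS_moderate", "non_TS")))
  data.table::data.table(
    gene_id = rownames(panel),
    spm_testis = spm,
    category = category,
    passed_overlap_filter = TRUE
  )
}
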