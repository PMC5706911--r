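# Positional enrichment of testis-specific regulatory elements around
# TS-/CT-lncRNAs, and the enhancer-stratified correlation comparison.

#' Specification of a strand-aware flanking window
#'
#' Promoter and methylation windows are single upstream intervals from
#' `upstream_far` to `upstream_near` bp 5' of the strand-aware gene start
#' (defaults 5 kb-100 bp and 1 kb-100 bp); enhancer flanks span
#' `upstream_far` upstream of the start plus `downstream` beyond the
#' strand-aware gene end (defaults 20 kb + 5 kb).
#'
#' @param kind "promoter_window", "methylation_window" or "enhancer_flanks".
#' @param upstream_far,upstream_near,downstream window geometry in bp;
#'   defaults depend on `kind`.
#' @return a `window_spec` list.
#' @export
window_spec <- function(kind = c("promoter_window", "methylation_window",
                                 "enhancer_flanks"),
                        upstream_far = NULL, upstream_near = NULL,
                        downstream = NULL) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    promoter_window = list(far = 5000L, near = 100L, down = 0L),
    methylation_window = list(far = 1000L, near = 100L, down = 0L),
    enhancer_flanks = list(far = 20000L, near = 0L, down = 5000L)
  )
  upstream_far <- upstream_far %||% defaults$far
  upstream_near <- upstream_near %||% defaults$near
  downstream <- downstream %||% defaults$down
  assert_that(upstream_far > upstream_near && upstream_near >= 0,
              "window requires upstream_far > upstream_near >= 0", "config_error")
  assert_that(downstream >= 0, "window requires downstream >= 0", "config_error")
  structure(list(kind = kind, upstream_far = as.integer(upstream_far),
                 upstream_near = as.integer(upstream_near),
                 downstream = as.integer(downstream)),
            class = "window_spec")
}

#' Strand-aware flanking window intervals of one gene
#'
#' @param gene one row of a `gene_models` table.
#' @param spec a `window_spec`.
#' @return data.table of chrom/start/end intervals (0-based half-open,
#'   clipped at 0, gene body excluded; empty intervals dropped).
#' @export
gene_windows <- function(gene, spec) {
  fwd <- gene$strand == "+"
  if (spec$kind == "enhancer_flanks") {
    if (fwd) {
      s <- c(gene$start - spec$upstream_far, gene$end)
      e <- c(gene$start, gene$end + spec$downstream)
    } else {
      s <- c(gene$end, gene$start - spec$downstream)
      e <- c(gene$end + spec$upstream_far, gene$start)
    }
  } else {
    if (fwd) {
      s <- gene$start - spec$upstream_far
      e <- gene$start - spec$upstream_near
    } else {
      s <- gene$end + spec$upstream_near
      e <- gene$end + spec$upstream_far
    }
  }
  s <- pmax(0L, as.integer(s)); e <- pmax(0L, as.integer(e))
  keep <- s < e
  data.table::data.table(chrom = gene$chrom, start = s[keep], end = e[keep])
}

#' Flag genes with a regulatory element in their window
#'
#' A gene is flagged when at least one element overlaps (>= 1 bp, strandless,
#' half-open) any of its window intervals.
#'
#' @param genes `gene_models`.
#' @param elements BED6-style table (chrom, start, end).
#' @param spec a `window_spec`.
#' @return named logical vector by gene id.
#' @export
element_presence <- function(genes, elements, spec) {
  out <- stats::setNames(rep(FALSE, nrow(genes)), genes$gene_id)
  if (nrow(elements) == 0 || nrow(genes) == 0) return(out)
  wins <- lapply(seq_len(nrow(genes)), function(i) gene_windows(genes[i, ], spec))
  nwin <- vapply(wins, nrow, integer(1))
  win_dt <- data.table::rbindlist(wins)
  if (nrow(win_dt) == 0) return(out)
  win_gr <- GenomicRanges::GRanges(win_dt$chrom,
                                   IRanges::IRanges(win_dt$start + 1L, win_dt$end))
  el_gr <- GenomicRanges::GRanges(elements$chrom,
                                  IRanges::IRanges(elements$start + 1L, elements$end))
  hits <- GenomicRanges::findOverlaps(win_gr, el_gr, minoverlap = 1L)
  owner <- rep(seq_len(nrow(genes)), nwin)
  out[unique(owner[S4Vectors::queryHits(hits)])] <- TRUE
  out
}

#' Window enrichment of elements near target versus background genes
#'
#' Two-sided Fisher's exact test on (target vs background) x (element
#' present vs absent); target genes are removed from the background first.
#'
#' @param genes `gene_models` covering both sets.
#' @param targets,background character vectors of gene ids.
#' @param elements BED6-style element table.
#' @param spec a `window_spec`.
#' @return list with `p.value`, `odds.ratio` (sample ad/bc),
#'   `odds.ratio.haldane`, `table`, `presence` (the per-gene flags).
#' @export
window_enrichment <- function(genes, targets, background, elements, spec) {
  background <- setdiff(background, targets)
  assert_that(length(targets) > 0 && length(background) > 0,
              "window enrichment needs non-empty target and background sets",
              "config_error")
  use <- genes[genes$gene_id %in% c(targets, background), ]
  pres <- element_presence(use, elements, spec)
  is_t <- names(pres) %in% targets
  ft <- fisher_exact_2x2(sum(pres[is_t]), sum(!pres[is_t]),
                         sum(pres[!is_t]), sum(!pres[!is_t]))
  ft$presence <- pres
  ft
}

#' Compare lncRNA-nearest-gene correlation between enhancer strata
#'
#' For each (lncRNA, nearest testis-specific coding gene) pair, Spearman rho
#' over the testis samples; a two-sided Wilcoxon rank-sum test then compares
#' the rho distributions between lncRNAs with and without a nearby enhancer.
#'
#' @param pairs data.frame with columns lncrna, coding.
#' @param expr_testis `expr_matrix` (or plain matrix) restricted to testis
#'   samples, containing both pair members.
#' @param enhancer_presence named logical by lncRNA id.
#' @return list with `rho` (per-pair table), `statistic`, `p.value`.
#' @export
enhancer_stratified_correlation <- function(pairs, expr_testis,
                                            enhancer_presence) {
  pairs <- data.table::as.data.table(pairs)
  assert_that(nrow(pairs) > 0, "no lncRNA / nearest-gene pairs", "config_error")
  x <- unclass(expr_testis)
  rho <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- x[pairs$lncrna[i], ]; b <- x[pairs$coding[i], ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    spearman_rho(a, b)
  }, numeric(1))
  with_enh <- enhancer_presence[pairs$lncrna]
  keep <- !is.na(rho) & !is.na(with_enh)
  rho <- rho[keep]; with_enh <- with_enh[keep]
  assert_that(any(with_enh) && any(!with_enh),
              "both enhancer strata must be non-empty", "config_error")
  w <- wilcox_rank_sum(rho[with_enh], rho[!with_enh])
  list(rho = data.table::data.table(pairs[keep, ], rho = rho,
                                    with_enhancer = with_enh),
       statistic = w$statistic, p.value = w$p.value)
}
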