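# Evolutionary conservation scoring: promoter definition, PhyloP rescaling,
# length-weighted region means over bedGraph tracks, and the rank-sum group
# comparison.

#' Promoter region of a gene
#'
#' 2 kb upstream and 0.5 kb downstream of the strand-aware transcript start
#' (the gene's 5'-most coordinate), clipped at 0: `[start-2000, start+500)`
#' on the plus strand, `[end-500, end+2000)` on the minus strand.
#'
#' @param gene one row of a `gene_models` table.
#' @param upstream,downstream window sizes in bp.
#' @return list with chrom, start, end (0-based half-open).
#' @export
promoter_region <- function(gene, upstream = 2000L, downstream = 500L) {
  if (gene$strand == "+") {
    s <- max(0L, gene$start - upstream); e <- gene$start + downstream
  } else {
    s <- max(0L, gene$end - downstream); e <- gene$end + upstream
  }
  list(chrom = gene$chrom, start = as.integer(s), end = as.integer(e))
}

#' Rescale a raw PhyloP score onto (0, 1)
#'
#' \eqn{1 - 0.5 \times 10^{-raw}} for positive raw scores and
#' \eqn{0.5 \times 10^{raw}} for negative ones; a raw score of 0 (undefined
#' by the piecewise formula) maps to 0.5, the common limit of both branches.
#' Strictly increasing, antisymmetric around (0, 0.5), so higher rescaled
#' values always mean higher conservation.
#'
#' @param raw finite numeric vector of raw PhyloP scores.
#' @return rescaled scores in (0, 1).
#' @examples
#' rescale_phylop(c(1, -1, 0)) # 0.95 0.05 0.50
#' @export
rescale_phylop <- function(raw) {
  if (any(!is.finite(raw))) {
    ctl_stop("raw PhyloP scores must be finite", "domain_error")
  }
  ifelse(raw > 0, 1 - 0.5 * 10^(-raw), 0.5 * 10^raw)
}

#' Length-weighted mean track score over a set of intervals
#'
#' Intervals are reduced to their union; every covered base contributes its
#' track value. Bases with no track coverage contribute per
#' `missing_policy`: "skip" drops them from the average, "zero" counts them
#' as 0.
#'
#' @param track a `score_track`.
#' @param intervals data.frame with chrom, start, end (0-based half-open).
#' @param missing_policy "skip" or "zero".
#' @return the mean score.
#' @export
mean_region_score <- function(track, intervals, missing_policy = c("skip", "zero")) {
  missing_policy <- match.arg(missing_policy)
  iv <- data.table::as.data.table(intervals)
  assert_that(nrow(iv) > 0 && all(iv$start < iv$end),
              "mean over an empty interval union is undefined", "domain_error")
  q <- GenomicRanges::reduce(GenomicRanges::GRanges(
    iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end)))
  tr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               value = track$value)
  hits <- GenomicRanges::findOverlaps(q, tr)
  ov <- GenomicRanges::pintersect(q[S4Vectors::queryHits(hits)],
                                  tr[S4Vectors::subjectHits(hits)])
  covered <- sum(GenomicRanges::width(ov))
  total <- sum(GenomicRanges::width(q))
  weight_sum <- sum(GenomicRanges::width(ov) *
                      tr$value[S4Vectors::subjectHits(hits)])
  denom <- if (missing_policy == "zero") total else covered
  if (denom == 0) {
    ctl_stop("no track coverage over the requested intervals", "domain_error")
  }
  weight_sum / denom
}

#' Conservation summary of genes over exons and promoter
#'
#' @param genes `gene_models`.
#' @param phastcons,phylop `score_track`s (PhyloP values are rescaled with
#'   [rescale_phylop()] before averaging).
#' @param missing_policy see [mean_region_score()].
#' @return data.table with gene_id, region ("exons"/"promoter"),
#'   mean_phastcons, mean_phylop_rescaled.
#' @export
conservation_summary <- function(genes, phastcons, phylop,
                                 missing_policy = "skip") {
  py <- data.table::copy(phylop)
  py$value <- rescale_phylop(py$value)
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    ex <- data.table::data.table(chrom = genes$chrom[i],
                                 start = genes$exons_start[[i]],
                                 end = genes$exons_end[[i]])
    pr <- promoter_region(genes[i, ])
    pr <- data.table::data.table(chrom = pr$chrom, start = pr$start, end = pr$end)
    score <- function(iv) {
      c(tryCatch(mean_region_score(phastcons, iv, missing_policy),
                 ctlnc_domain_error = function(e) NA_real_),
        tryCatch(mean_region_score(py, iv, missing_policy),
                 ctlnc_domain_error = function(e) NA_real_))
    }
    sx <- score(ex); sp <- score(pr)
    data.table::data.table(
      gene_id = genes$gene_id[i],
      region = c("exons", "promoter"),
      mean_phastcons = c(sx[1], sp[1]),
      mean_phylop_rescaled = c(sx[2], sp[2])
    )
  })
  data.table::rbindlist(rows)
}

#' Compare conservation summaries between two gene groups
#'
#' Two-sided Wilcoxon rank-sum test (exact for combined n <= 20 without
#' ties, tie-corrected normal approximation otherwise) on a summary column.
#'
#' @param summaries_a,summaries_b numeric vectors of per-gene summary scores
#'   (NAs dropped).
#' @return list with `statistic`, `p.value`, `exact`.
#' @export
compare_groups <- function(summaries_a, summaries_b) {
  wilcox_rank_sum(summaries_a, summaries_b)
}
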