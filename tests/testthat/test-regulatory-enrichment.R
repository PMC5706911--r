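# Strand-aware windows, element presence, window enrichment, and the
# enhancer-stratified correlation comparison.

test_that("gene windows follow the printed geometries", {
  gp <- make_genes(data.frame(gene_id = "g", start = 100000L, end = 103000L))
  w <- gene_windows(gp[1, ], window_spec("promoter_window"))
  expect_equal(c(w$start, w$end), c(95000L, 99900L))
  wm <- gene_windows(gp[1, ], window_spec("methylation_window"))
  expect_equal(c(wm$start, wm$end), c(99000L, 99900L))

  gm <- make_genes(data.frame(gene_id = "g", start = 10000L, end = 20000L,
                              strand = "-"))
  we <- gene_windows(gm[1, ], window_spec("enhancer_flanks"))
  expect_equal(we$start, c(20000L, 5000L))
  expect_equal(we$end, c(40000L, 10000L))

  wp <- gene_windows(gm[1, ], window_spec("promoter_window"))
  expect_equal(c(wp$start, wp$end), c(20100L, 25000L))
  # clipping at the chromosome origin
  g0 <- make_genes(data.frame(gene_id = "g", start = 3000L, end = 5000L))
  w0 <- gene_windows(g0[1, ], window_spec("enhancer_flanks"))
  expect_equal(w0$start[1], 0L)
  expect_error(window_spec("promoter_window", upstream_far = 100,
                           upstream_near = 100),
               class = "ctlnc_config_error")
})

test_that("element presence respects the half-open convention and grows with windows", {
  g <- make_genes(data.frame(gene_id = "g", start = 100000L, end = 103000L))
  ws <- window_spec("promoter_window")      # window [95000, 99900)
  abut <- data.frame(chrom = "chr1", start = 99900L, end = 99950L, name = "e")
  expect_false(element_presence(g, abut, ws)[["g"]])
  inside <- data.frame(chrom = "chr1", start = 99899L, end = 99950L, name = "e")
  expect_true(element_presence(g, inside, ws)[["g"]])
  expect_false(element_presence(g, inside[0, ], ws)[["g"]])
  # enlarging the window never turns a present flag absent
  set.seed(40)
  for (i in 1:20) {
    s <- sample(90000:110000, 1)
    el <- data.frame(chrom = "chr1", start = s, end = s + 200L, name = "e")
    small <- element_presence(g, el, window_spec("enhancer_flanks",
                                                 upstream_far = 5000,
                                                 downstream = 1000))[["g"]]
    big <- element_presence(g, el, window_spec("enhancer_flanks"))[["g"]]
    expect_true(!small || big)
  }
})

test_that("window enrichment matches enumeration and detects planted designs", {
  g <- make_genes(data.frame(
    gene_id = sprintf("g%02d", 1:20),
    start = seq(100000L, by = 100000L, length.out = 20),
    end = seq(103000L, by = 100000L, length.out = 20)))
  ws <- window_spec("promoter_window")
  # put an element in the promoter window of the first 10 genes
  els <- data.frame(chrom = "chr1",
                    start = g$start[1:10] - 2000L,
                    end = g$start[1:10] - 1800L,
                    name = sprintf("e%d", 1:10))
  res <- window_enrichment(g, g$gene_id[1:10], g$gene_id[11:20], els, ws)
  expect_equal(res$p.value, fisher_oracle(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(res$p.value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_error(window_enrichment(g, character(0), g$gene_id, els, ws),
               class = "ctlnc_config_error")
})

test_that("window enrichment is invariant under genome mirroring", {
  spec <- small_spec(seed = 9L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  an <- generate_annotation(spec, tc$truth)
  truth <- an$truth
  genes <- an$genes
  els <- an$elements$enhancer
  ws <- window_spec("enhancer_flanks")
  lnc <- genes$gene_id[grepl("^LNC", genes$gene_id)]
  bg <- setdiff(lnc, truth$ts_genes)
  fwd <- window_enrichment(genes, truth$ts_genes, bg, els, ws)

  L <- max(c(genes$end, els$end)) + 10000L
  mg <- data.table::copy(genes)
  mg$start <- L - genes$end; mg$end <- L - genes$start
  mg$strand <- ifelse(genes$strand == "+", "-", "+")
  mg$exons_start <- lapply(seq_len(nrow(genes)), function(i)
    rev(L - genes$exons_end[[i]]))
  mg$exons_end <- lapply(seq_len(nrow(genes)), function(i)
    rev(L - genes$exons_start[[i]]))
  mg <- gene_models(mg)
  mels <- data.table::copy(els)
  mels$start <- L - els$end; mels$end <- L - els$start
  rev_res <- window_enrichment(mg, truth$ts_genes, bg, mels, ws)
  expect_identical(fwd$p.value, rev_res$p.value)
  expect_identical(fwd$presence[names(rev_res$presence)], rev_res$presence)
})

test_that("planted synthetic elements land in their windows and enrich", {
  spec <- small_spec(seed = 10L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  an <- generate_annotation(spec, tc$truth)
  truth <- an$truth
  genes <- an$genes
  kinds <- c(promoter = "promoter_window", methylation = "methylation_window",
             enhancer = "enhancer_flanks")
  for (kind in names(kinds)) {
    ws <- window_spec(kinds[[kind]])
    pres <- element_presence(genes, an$elements[[kind]], ws)
    targets <- unname(truth$element_placements[
      startsWith(names(truth$element_placements),
                 c(promoter = "PROM_", methylation = "METH_",
                   enhancer = "ENH_")[[kind]])])
    targets <- setdiff(targets, "background")
    expect_true(all(pres[targets]))
  }
})

test_that("enhancer-stratified correlation separates planted strata", {
  set.seed(26)
  n <- 40                                  # testis samples
  make_pairs <- function(rho, k, off) {
    lapply(seq_len(k), function(i) {
      f <- rnorm(n)
      lnc <- 2^(3 + f)
      cod <- 2^(3 + rho * f + sqrt(1 - rho^2) * rnorm(n))
      list(lnc = lnc, cod = cod,
           lid = sprintf("L%02d", off + i), cid = sprintf("C%02d", off + i))
    })
  }
  no_enh <- make_pairs(0.8, 30, 0)
  with_enh <- make_pairs(0.2, 30, 30)
  all <- c(no_enh, with_enh)
  mat <- do.call(rbind, lapply(all, function(p) rbind(p$lnc, p$cod)))
  rownames(mat) <- unlist(lapply(all, function(p) c(p$lid, p$cid)))
  colnames(mat) <- sprintf("s%d", 1:n)
  pairs <- data.frame(lncrna = vapply(all, `[[`, "", "lid"),
                      coding = vapply(all, `[[`, "", "cid"))
  enh <- stats::setNames(c(rep(FALSE, 30), rep(TRUE, 30)), pairs$lncrna)
  res <- enhancer_stratified_correlation(pairs, mat, enh)
  expect_lt(res$p.value, 0.01)
  expect_gt(mean(res$rho$rho[!res$rho$with_enhancer]),
            mean(res$rho$rho[res$rho$with_enhancer]))
  # identical strata: exact p = 1 at one pair per stratum
  two <- pairs[c(1, 31), ]
  res2 <- enhancer_stratified_correlation(two, mat,
                                          enh[c(two$lncrna)])
  expect_equal(res2$p.value, 1)
  expect_error(enhancer_stratified_correlation(pairs[1:3, ], mat,
                                               enh[pairs$lncrna[1:3]]),
               class = "ctlnc_config_error")
})
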