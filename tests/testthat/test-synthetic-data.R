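# The synthetic-cohort generator: validation, determinism, truth nesting,
# and the planted statistical structure downstream stages rely on.

test_that("cohort_spec validation names the offending field", {
  err <- tryCatch(cohort_spec(frac_ts = 1.2), condition = identity)
  expect_s3_class(err, "ctlnc_config_error")
  expect_match(conditionMessage(err), "frac_ts")
  err2 <- tryCatch(cohort_spec(n_genes = 0), condition = identity)
  expect_match(conditionMessage(err2), "n_genes")
  expect_error(cohort_spec(activation_log2_effect = -1),
               class = "ctlnc_config_error")
  expect_error(cohort_spec(n_lncrna = 500, n_genes = 500),
               class = "ctlnc_config_error")
  spec <- cohort_spec()
  expect_equal(sum(spec$tissues == "testis"), 1L)
})

test_that("generators are pure functions of the seed", {
  spec <- small_spec(seed = 7L)
  a <- generate_normal_panel(spec)
  b <- generate_normal_panel(spec)
  expect_identical(unclass(a$panel), unclass(b$panel))
  expect_identical(a$truth$ts_genes, b$truth$ts_genes)
  ta <- generate_tumor_cohorts(spec, a$truth)
  tb <- generate_tumor_cohorts(spec, b$truth)
  expect_identical(lapply(ta$cohorts, unclass), lapply(tb$cohorts, unclass))
  an_a <- generate_annotation(spec, ta$truth)
  an_b <- generate_annotation(spec, tb$truth)
  expect_identical(an_a$elements, an_b$elements)
  expect_identical(an_a$phastcons$value, an_b$phastcons$value)
  # file-level determinism
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_cohort(spec, d1); s2 <- simulate_cohort(spec, d2)
  for (f in names(s1$files)) {
    expect_identical(readLines(s1$files[[f]]), readLines(s2$files[[f]]),
                     info = f)
  }
})

test_that("truth nesting and zero-fraction edge cases hold", {
  spec <- small_spec(seed = 2L)
  tr <- generate_normal_panel(spec)$truth
  expect_true(all(tr$eect_genes %in% tr$ct_genes))
  expect_true(all(tr$ct_genes %in% tr$ts_genes))

  sp0 <- small_spec(seed = 2L, frac_ts = 0)
  tr0 <- generate_normal_panel(sp0)$truth
  expect_length(tr0$ts_genes, 0L)

  sp1 <- small_spec(seed = 2L, frac_ts = 1, dropout_rate = 0)
  np1 <- generate_normal_panel(sp1)
  tissue <- np1$tissues$tissue[match(colnames(np1$panel), np1$tissues$sample_id)]
  lnc <- grepl("^LNC", rownames(np1$panel))
  m_test <- rowMeans(unclass(np1$panel)[lnc, tissue == "testis"])
  m_rest <- rowMeans(unclass(np1$panel)[lnc, tissue != "testis"])
  expect_true(all(m_test > m_rest))
})

test_that("truth/spec mismatch raises a consistency error", {
  spec <- small_spec(seed = 3L)
  other <- small_spec(seed = 4L)
  tr <- generate_normal_panel(spec)$truth
  expect_error(generate_tumor_cohorts(other, tr),
               class = "ctlnc_consistency_error")
  expect_error(generate_methylation_mutations_clinical(spec, tr),
               class = "ctlnc_consistency_error")  # tumor stash missing
})

test_that("planted modules carry the requested rank correlation", {
  spec <- small_spec(seed = 11L, rho_within = 0.9, module_size = 10L,
                     n_tumor_samples_per_type = 150L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  truth <- tc$truth
  x <- unclass(tc$cohorts[[1]])
  mods <- split(names(truth$module_assignment), truth$module_assignment)
  within <- c(); between <- c()
  for (m in mods) {
    cm <- stats::cor(t(x[m, ]), method = "spearman")
    within <- c(within, cm[upper.tri(cm)])
  }
  cb <- stats::cor(t(x[mods[[1]], ]), t(x[mods[[2]], ]), method = "spearman")
  between <- as.vector(cb)
  expect_gt(median(within), median(between))
  expect_gt(median(within), 0.7)
  expect_lt(abs(median(between)), 0.2)
})

test_that("planted elements obey strand-aware coordinate arithmetic", {
  spec <- small_spec(seed = 13L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  an <- generate_annotation(spec, tc$truth)
  genes <- an$genes
  # minus-strand enhancer targets: element within 20 kb beyond the genomic
  # end (strand-aware upstream) or within 5 kb before the genomic start
  enh <- an$elements$enhancer
  planted <- enh[!startsWith(enh$name, "BG_"), ]
  for (i in seq_len(nrow(planted))) {
    target <- sub("^ENH_", "", planted$name[i])
    g <- genes[genes$gene_id == target, ]
    if (g$strand == "-") {
      up <- planted$start[i] >= g$end & planted$end[i] <= g$end + 20000L
      down <- planted$start[i] >= g$start - 5000L & planted$end[i] <= g$start
      expect_true(up || down)
    } else {
      up <- planted$start[i] >= g$start - 20000L & planted$end[i] <= g$start
      down <- planted$start[i] >= g$end & planted$end[i] <= g$end + 5000L
      expect_true(up || down)
    }
  }
  # promoter / methylation elements in their upstream bands
  for (kind in c("promoter", "methylation")) {
    far <- if (kind == "promoter") 5000L else 1000L
    pref <- if (kind == "promoter") "PROM_" else "METH_"
    tab <- an$elements[[kind]]
    tab <- tab[!startsWith(tab$name, "BG_"), ]
    for (i in seq_len(nrow(tab))) {
      g <- genes[genes$gene_id == sub(pref, "", tab$name[i]), ]
      if (g$strand == "+") {
        expect_true(tab$start[i] >= g$start - far &&
                      tab$end[i] <= g$start - 100L)
      } else {
        expect_true(tab$start[i] >= g$end + 100L &&
                      tab$end[i] <= g$end + far)
      }
    }
  }
  # background elements never fall in any window
  for (kind in names(an$elements)) {
    ws <- window_spec(c(promoter = "promoter_window",
                        methylation = "methylation_window",
                        enhancer = "enhancer_flanks")[[kind]])
    bg <- an$elements[[kind]][startsWith(an$elements[[kind]]$name, "BG_"), ]
    pres <- element_presence(genes, bg, ws)
    expect_false(any(pres))
  }
})

test_that("conservation tracks and gene sets have the declared shape", {
  spec <- small_spec(seed = 14L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  an <- generate_annotation(spec, tc$truth)
  expect_true(all(an$phastcons$value >= 0 & an$phastcons$value <= 1))
  expect_equal(length(an$gmt), spec$n_terms)
  planted <- unname(an$truth$planted_terms)
  for (m in names(an$truth$planted_terms)) {
    members <- names(an$truth$module_assignment)[an$truth$module_assignment == m]
    expect_setequal(an$gmt[[an$truth$planted_terms[[m]]]],
                    grep("^PC", members, value = TRUE))
  }
})

test_that("methylation is shifted down in activated samples, flat when off", {
  spec <- small_spec(seed = 15L, n_tumor_samples_per_type = 250L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  truth <- tc$truth
  mm <- generate_methylation_mutations_clinical(spec, truth)
  type <- names(truth$tumor)[1]
  act <- truth$tumor[[type]]$activated
  g <- truth$eect_genes[which.max(rowSums(act))]
  betas <- mm$methylation[sprintf("meth_%s", g), colnames(act)]
  expect_lt(mean(betas[act[g, ]]), mean(betas[!act[g, ]]))

  sp0 <- small_spec(seed = 15L, n_tumor_samples_per_type = 250L,
                    methylation_effect_size = 0)
  np0 <- generate_normal_panel(sp0)
  tc0 <- generate_tumor_cohorts(sp0, np0$truth)
  mm0 <- generate_methylation_mutations_clinical(sp0, tc0$truth)
  act0 <- tc0$truth$tumor[[1]]$activated
  g0 <- tc0$truth$eect_genes[which.max(rowSums(act0))]
  b0 <- mm0$methylation[sprintf("meth_%s", g0), colnames(act0)]
  on <- b0[act0[g0, ]]; off <- b0[!act0[g0, ]]
  se <- sqrt(stats::var(on) / length(on) + stats::var(off) / length(off))
  expect_lt(abs(mean(on) - mean(off)), 3 * se + 1e-9)
})

test_that("exclusive pairs have (near) zero activation among mutated samples", {
  spec <- small_spec(seed = 16L, activation_frequency = 0.3,
                     n_exclusive_pairs = 2L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  truth <- tc$truth
  for (type in names(truth$tumor)) {
    act <- truth$tumor[[type]]$activated
    mut <- truth$tumor[[type]]$mutations
    for (i in seq_len(nrow(truth$exclusive_pairs))) {
      l <- truth$exclusive_pairs$lncrna[i]
      d <- truth$exclusive_pairs$driver[i]
      expect_equal(sum(act[l, mut[, d]]), 0L)
    }
  }
})

test_that("downstream calls are invariant to sample order (label shuffle)", {
  spec <- small_spec(seed = 18L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  set.seed(99)
  perm <- sample(ncol(np$panel))
  panel_p <- expression_matrix(unclass(np$panel)[, perm], "RPKM")
  a <- classify_testis_specific(np$panel, np$tissues)
  b <- classify_testis_specific(panel_p, np$tissues)
  expect_equal(a, b)
})
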