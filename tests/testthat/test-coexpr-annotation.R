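# Guilt-by-association machinery: expression filter, partner selection,
# per-lncRNA enrichment, database expansion and CT-set enrichment.

test_that("expression filter keeps genes above the floor in >= 1% of samples", {
  v <- rbind(c(rep(0, 99), 6),          # >5 in exactly 1% -> kept
             rep(0, 100),               # all zero -> removed
             rep(5, 100))               # exactly at floor -> removed
  x <- expr_fixture(v, unit = "normalized_read_counts")
  kept <- expression_filter(x)
  expect_equal(kept, "g1")
  expect_equal(length(expression_filter(x, floor = 0, min_frac = 0)), 3L)
})

test_that("top-decile partners are sized by floor and order-invariant", {
  set.seed(4)
  rho <- stats::setNames(runif(100, -1, 1), sprintf("pc%03d", 1:100))
  prof <- top_decile_partners(rho, "lnc1")
  expect_equal(nrow(prof$partners_pos), 10L)
  expect_equal(nrow(prof$partners_neg), 10L)
  expect_equal(prof$partners_pos$gene[1], names(rho)[which.max(rho)])
  expect_equal(prof$partners_neg$gene[1], names(rho)[which.min(rho)])
  perm <- top_decile_partners(rho[sample(100)], "lnc1")
  expect_equal(sort(perm$partners_pos$gene), sort(prof$partners_pos$gene))
  expect_equal(sort(perm$partners_neg$gene), sort(prof$partners_neg$gene))
  # boundary ties broken lexicographically
  tied <- stats::setNames(c(1, rep(0.5, 5), rep(-1, 14)),
                          sprintf("g%02d", 20:1))
  pt <- top_decile_partners(tied, "lnc2")
  expect_equal(nrow(pt$partners_pos), 2L)
  expect_equal(pt$partners_pos$gene[2], "g15")  # smallest id among the 0.5 ties
  expect_error(top_decile_partners(rho[1:9]), class = "ctlnc_config_error")
})

test_that("per-lncRNA annotation matches the enumeration oracle", {
  universe <- sprintf("pc%03d", 1:60)
  terms <- list(T1 = universe[1:8], T2 = universe[9:40])
  db <- annotation_db(terms, universe)
  prof <- structure(list(
    lncrna_id = "l1",
    partners_pos = data.table::data.table(gene = universe[1:6], rho = 0.9),
    partners_neg = data.table::data.table(gene = universe[41:46], rho = -0.9)
  ), class = "coexpression_profile")
  ann <- annotate_lncrna(prof, db, alpha = 0.01)
  t1 <- ann$table[ann$table$term == "T1", ]
  expect_equal(t1$N, 60L); expect_equal(t1$M, 8L)
  expect_equal(t1$n, 12L); expect_equal(t1$m, 6L)
  expect_equal(t1$p_raw, hyper_tail_oracle(60, 8, 12, 6), tolerance = 1e-12)
  expect_true("T1" %in% ann$terms)
  expect_false("T2" %in% ann$terms)
  # alpha = 1 assigns every term with at least one hit
  all_terms <- annotate_lncrna(prof, db, alpha = 1.000)$terms
  hit_terms <- ann$table$term[ann$table$m >= 1]
  expect_setequal(all_terms, hit_terms)
  # empty partner set: empty annotation, not an error
  empty <- structure(list(lncrna_id = "l0",
                          partners_pos = data.table::data.table(gene = character(0), rho = numeric(0)),
                          partners_neg = data.table::data.table(gene = character(0), rho = numeric(0))),
                     class = "coexpression_profile")
  expect_length(annotate_lncrna(empty, db)$terms, 0L)
})

test_that("uniform partners are rarely annotated (null calibration)", {
  set.seed(19)
  universe <- sprintf("pc%03d", 1:200)
  terms <- lapply(1:20, function(i) sample(universe, 25))
  names(terms) <- sprintf("T%02d", 1:20)
  db <- annotation_db(terms, universe)
  n_annot <- 0; reps <- 60
  for (i in seq_len(reps)) {
    q <- sample(universe, 40)
    prof <- structure(list(lncrna_id = "l",
                           partners_pos = data.table::data.table(gene = q[1:20], rho = 1),
                           partners_neg = data.table::data.table(gene = q[21:40], rho = -1)),
                      class = "coexpression_profile")
    if (length(annotate_lncrna(prof, db, alpha = 0.05)$terms) > 0) {
      n_annot <- n_annot + 1
    }
  }
  expect_lte(n_annot / reps, 0.05 + 2.5 * sqrt(0.05 * 0.95 / reps))
})

test_that("database expansion updates N and M and is idempotent", {
  db <- annotation_db(list(T1 = c("a", "b"), T2 = c("c")), c("a", "b", "c"))
  same <- expand_db(db, list())
  expect_equal(same$terms, db$terms)
  expect_equal(same$universe, db$universe)
  ex <- expand_db(db, list(lnc1 = "T1"))
  expect_equal(length(ex$universe), length(db$universe) + 1L)
  expect_equal(length(ex$terms$T1), length(db$terms$T1) + 1L)
  expect_equal(length(ex$terms$T2), length(db$terms$T2))
  twice <- expand_db(ex, list(lnc1 = "T1"))
  expect_equal(twice, ex)
  expect_error(expand_db(db, list(lnc1 = "NOPE")), class = "ctlnc_config_error")
})

test_that("CT-set enrichment ranks a planted term first and errors on n = 0", {
  universe <- c(sprintf("pc%02d", 1:50), sprintf("l%02d", 1:10))
  terms <- list(T1 = c(sprintf("pc%02d", 1:5), sprintf("l%02d", 1:6)),
                T2 = sprintf("pc%02d", 6:30))
  db <- annotation_db(terms, universe)
  ct <- sprintf("l%02d", 1:6)
  res <- ct_set_enrichment(ct, db)
  expect_equal(res$term[1], "T1")
  expect_equal(res$p_raw[1], hyper_tail_oracle(60, 11, 6, 6), tolerance = 1e-12)
  expect_error(ct_set_enrichment(c("zz1", "zz2"), db),
               class = "ctlnc_config_error")
})

test_that("module lncRNAs recover their planted terms on synthetic data", {
  spec <- small_spec(seed = 6L, n_tumor_samples_per_type = 100L)
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  an <- generate_annotation(spec, tc$truth)
  truth <- an$truth
  res <- annotate_lncrna_set(tc$cohorts[[1]], truth$ct_genes, an$gmt)
  hit <- vapply(truth$module_lnc, function(l) {
    planted <- truth$planted_terms[[truth$module_assignment[[l]]]]
    got <- res$annotations[[l]]
    !is.null(got) && planted %in% got
  }, logical(1))
  expect_gte(mean(hit), 0.8)
  cte <- ct_set_enrichment(truth$ct_genes, res$expanded_db)
  planted <- unname(truth$planted_terms)
  expect_true(all(match(planted, cte$term) <= length(planted)))
})
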