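# Covariate-adjusted linear models, the oncogene group comparison and the
# mutation mutual-exclusivity screen.

#' Ordinary least squares with complete-case handling
#'
#' Categorical covariates are dummy-coded against the first level in sorted
#' order; rows with missing values in the response or any covariate are
#' dropped; a rank-deficient design is an error naming the collinear terms.
#' Factors that collapse to a single level after complete-case filtering are
#' dropped from the model (with a message), since they carry no contrast.
#'
#' @param response numeric vector.
#' @param covariates data.frame of numeric and character/factor columns,
#'   same length as `response`.
#' @return a `regression_fit`: list with `terms` (data.table term, beta,
#'   se, t, p), `n_used`, `adjustment`, `r_squared`, and the `lm` object.
#' @export
ols_fit <- function(response, covariates) {
  covariates <- as.data.frame(covariates)
  assert_that(nrow(covariates) == length(response),
              "response and covariates must have the same length", "config_error")
  df <- data.frame(.y = response, covariates, check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  for (nm in names(covariates)) {
    v <- df[[nm]]
    if (is.character(v) || is.factor(v)) {
      lv <- sort(unique(as.character(v)))
      if (length(lv) < 2) {
        message(sprintf("ols_fit: dropping single-level covariate '%s'", nm))
        df[[nm]] <- NULL
        next
      }
      df[[nm]] <- factor(as.character(v), levels = lv)
    }
  }
  preds <- setdiff(names(df), ".y")
  assert_that(length(preds) > 0, "no usable covariates", "config_error")
  form <- stats::as.formula(paste("`.y` ~", paste(sprintf("`%s`", preds),
                                                  collapse = " + ")))
  assert_that(nrow(df) > length(preds) + 1,
              "more parameters than observations", "config_error")
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    ctl_stop("rank-deficient design; collinear term(s): %s", "config_error",
             paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                   collapse = ", "))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    terms = data.table::data.table(term = rownames(co), beta = co[, 1],
                                   se = co[, 2], t = co[, 3], p = co[, 4]),
    n_used = nrow(df),
    adjustment = preds,
    r_squared = sm$r.squared,
    lm = fit
  ), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf("<regression_fit> n = %d, R^2 = %.3f\n", x$n_used, x$r_squared))
  print(x$terms)
  invisible(x)
}

#' Coefficient row of a fitted term
#' @param fit a `regression_fit`.
#' @param term term name (matched by prefix for factor terms).
#' @export
fit_term <- function(fit, term) {
  idx <- which(fit$terms$term == term)
  hit <- fit$terms[idx, ]
  assert_that(nrow(hit) == 1, "term '%s' not in the fit", "config_error", term)
  hit
}

stage_to_numeric <- function(stage) {
  if (is.numeric(stage)) return(stage)
  m <- c(I = 1, II = 2, III = 3, IV = 4)
  out <- m[as.character(stage)]
  unname(out)
}

#' Activated-count versus AJCC stage, covariate-adjusted
#'
#' Fits `n_activated_eect ~ stage + age + gender + cancer_type` with stage
#' numeric 1-4 (the linear-trend claim) and gender/cancer_type categorical.
#'
#' @param counts data.frame with sample_id, n_activated_eect.
#' @param clinical clinical table (sample_id, age, gender, stage,
#'   cancer_type; stage I-IV or 1-4).
#' @return a `regression_fit`.
#' @export
stage_association <- function(counts, clinical) {
  cnt <- data.table::as.data.table(counts)[, c("sample_id", "n_activated_eect")]
  d <- merge(cnt, data.table::as.data.table(clinical), by = "sample_id")
  stage <- stage_to_numeric(d$stage)
  assert_that(length(unique(stats::na.omit(stage))) >= 2,
              "need at least two distinct stages", "config_error")
  ols_fit(d$n_activated_eect,
          data.frame(stage = stage, age = d$age, gender = d$gender,
                     cancer_type = d$cancer_type))
}

#' SMG mutation ratio versus activated EECT count
#'
#' By default regresses the activated count on the SMG ratio with cancer
#' type as covariate; `orientation = "ratio_on_count"` flips response and
#' predictor. The sign of the association is orientation-invariant.
#'
#' @param smg_ratio per-sample ratio in \[0, 1\].
#' @param counts data.frame with sample_id, n_activated_eect aligned with
#'   `smg_ratio`.
#' @param cancer_type per-sample labels.
#' @param orientation "count_on_ratio" (default) or "ratio_on_count".
#' @return a `regression_fit`.
#' @export
smg_ratio_association <- function(smg_ratio, counts,
                                  cancer_type = NULL,
                                  orientation = c("count_on_ratio",
                                                  "ratio_on_count")) {
  orientation <- match.arg(orientation)
  assert_that(all(smg_ratio >= 0 & smg_ratio <= 1, na.rm = TRUE),
              "SMG mutation ratio must lie in [0, 1]", "config_error")
  n_act <- data.table::as.data.table(counts)$n_activated_eect
  cov <- if (orientation == "count_on_ratio") {
    data.frame(smg_ratio = smg_ratio)
  } else {
    data.frame(n_activated_eect = n_act)
  }
  if (!is.null(cancer_type) && length(unique(cancer_type)) >= 2) {
    cov$cancer_type <- cancer_type
  }
  resp <- if (orientation == "count_on_ratio") n_act else smg_ratio
  ols_fit(resp, cov)
}

#' Mean promoter methylation versus activated EECT count
#'
#' Regresses the activated count on the per-sample mean promoter beta of
#' all EECT-lncRNAs, adjusted for cancer type and optionally for the global
#' mean promoter methylation of all genes.
#'
#' @param mean_promoter_beta per-sample mean beta over EECT-lncRNA
#'   promoters, in \[0, 1\].
#' @param counts data.frame with sample_id, n_activated_eect.
#' @param cancer_type per-sample labels.
#' @param global_beta optional per-sample mean beta over all gene promoters.
#' @return a `regression_fit`.
#' @export
methylation_association <- function(mean_promoter_beta, counts,
                                    cancer_type = NULL, global_beta = NULL) {
  assert_that(all(mean_promoter_beta >= 0 & mean_promoter_beta <= 1,
                  na.rm = TRUE),
              "beta values must lie in [0, 1]", "config_error")
  assert_that(stats::sd(mean_promoter_beta, na.rm = TRUE) > 0,
              "methylation has no variance", "config_error")
  cov <- data.frame(mean_promoter_beta = mean_promoter_beta)
  if (!is.null(cancer_type) && length(unique(cancer_type)) >= 2) {
    cov$cancer_type <- cancer_type
  }
  if (!is.null(global_beta)) cov$global_beta <- global_beta
  ols_fit(data.table::as.data.table(counts)$n_activated_eect, cov)
}

#' Compare activated counts between oncogene-positive and -negative samples
#'
#' Two-sided Wilcoxon rank-sum test of the per-sample activated EECT count
#' between samples with and without activating driver mutations.
#'
#' @param counts per-sample activated counts (numeric).
#' @param group_labels "positive"/"negative" per sample.
#' @return list with `statistic`, `p.value`, `exact`.
#' @export
oncogene_group_test <- function(counts, group_labels) {
  assert_that(all(group_labels %in% c("positive", "negative")),
              "group labels must be 'positive' or 'negative'", "config_error")
  pos <- counts[group_labels == "positive"]
  neg <- counts[group_labels == "negative"]
  assert_that(length(pos) > 0 && length(neg) > 0,
              "both oncogene groups must be non-empty", "config_error")
  wilcox_rank_sum(pos, neg)
}

#' Mutation / activation mutual-exclusivity screen
#'
#' For every (lncRNA, driver) pair — plus a per-lncRNA aggregate against
#' "any driver mutated" — a two-sided Fisher's exact test on the 2x2 table
#' (mutated vs wild-type) x (activated vs inactive). Direction is
#' "exclusive" when the sample odds ratio is < 1, "co_occurring" when > 1.
#' Pairs with a zero-variance margin are skipped (recorded with a reason),
#' p-values are BH-adjusted across tested pairs.
#'
#' @param activation lncRNAs x samples logical matrix.
#' @param mutations samples x drivers logical matrix (same sample set).
#' @param alpha BH cutoff used to flag significant exclusive pairs.
#' @param include_aggregate also test each lncRNA against "any driver".
#' @return list with `results` (data.table: lncrna, driver, a/b/c/d cells,
#'   odds ratio, p_raw, p_bh, direction, significant_exclusive) and
#'   `skipped` (pair, reason).
#' @export
mutual_exclusivity_screen <- function(activation, mutations, alpha = 0.05,
                                      include_aggregate = TRUE) {
  assert_that(ncol(activation) == nrow(mutations) &&
                all(colnames(activation) == rownames(mutations)),
              "activation and mutation matrices must share the sample universe",
              "consistency_error")
  drivers <- colnames(mutations)
  muts <- mutations
  if (include_aggregate && ncol(mutations) > 0) {
    muts <- cbind(mutations, any_driver = rowSums(mutations) > 0)
  }
  rows <- list(); skipped <- list()
  for (l in rownames(activation)) {
    act <- activation[l, ]
    for (d in colnames(muts)) {
      mu <- muts[, d]
      if (all(act) || !any(act) || all(mu) || !any(mu)) {
        skipped[[length(skipped) + 1L]] <- data.table::data.table(
          lncrna = l, driver = d,
          reason = if (all(act) || !any(act)) "lncRNA activation has no variance"
                   else "driver mutation has no variance")
        next
      }
      a <- sum(mu & act); b <- sum(mu & !act)
      c_ <- sum(!mu & act); d_ <- sum(!mu & !act)
      ft <- fisher_exact_2x2(a, b, c_, d_)
      or <- ft$odds.ratio
      rows[[length(rows) + 1L]] <- data.table::data.table(
        lncrna = l, driver = d, mut_act = a, mut_inact = b,
        wt_act = c_, wt_inact = d_,
        odds_ratio = or, odds_ratio_haldane = ft$odds.ratio.haldane,
        p_raw = ft$p.value,
        direction = if (is.nan(or) || or == 1) "none"
                    else if (or < 1) "exclusive" else "co_occurring")
    }
  }
  results <- if (length(rows)) data.table::rbindlist(rows) else {
    data.table::data.table(lncrna = character(0), driver = character(0),
                           mut_act = integer(0), mut_inact = integer(0),
                           wt_act = integer(0), wt_inact = integer(0),
                           odds_ratio = numeric(0),
                           odds_ratio_haldane = numeric(0),
                           p_raw = numeric(0), direction = character(0))
  }
  if (nrow(results)) {
    results$p_bh <- bh_adjust(results$p_raw)
    results$significant_exclusive <- results$p_bh < alpha &
      results$direction == "exclusive"
    data.table::setorder(results, p_bh, p_raw)
  }
  list(results = results,
       skipped = if (length(skipped)) data.table::rbindlist(skipped) else
         data.table::data.table(lncrna = character(0), driver = character(0),
                                reason = character(0)))
}
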