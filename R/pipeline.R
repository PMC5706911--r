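# End-to-end orchestration: simulate (or read) the inputs, classify TS
# lncRNAs, call CT/EECT genes, score conservation, annotate by co-expression,
# test regulatory-element windows, fit the association models, and write a
# manifest with content hashes of every output.

#' Build and validate a pipeline configuration
#'
#' Exactly one data source: a `simulate` block (arguments for
#' [cohort_spec()]) or an `input_dir` holding files laid out as written by
#' [simulate_cohort()]. Stage toggles and thresholds default to the printed
#' analysis values (floor by unit dialect, 1% sample fraction, 3 x SD,
#' P_BH < 0.01, SPM cutoffs 0.9/0.6, promoter/methylation/enhancer windows
#' 100 bp-5 kb, 100 bp-1 kb, 20 kb + 5 kb).
#'
#' @param simulate named list of [cohort_spec()] arguments, or NULL.
#' @param input_dir directory of pre-generated inputs, or NULL.
#' @param outdir output directory.
#' @param seed integer seed (overrides the simulate block's seed).
#' @param stages named logical list toggling specificity, ct_calling,
#'   conservation, annotation, regulatory, association.
#' @param thresholds named list: min_frac, k_sd, alpha_annotation, spm_high,
#'   spm_moderate, floor (NULL = by unit).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = list(), input_dir = NULL,
                            outdir = tempfile("ctlnc_run_"),
                            seed = NULL, stages = list(),
                            thresholds = list()) {
  assert_that(xor(length(simulate) > 0 || is.null(input_dir), !is.null(input_dir)) ||
                is.null(input_dir),
              "configure exactly one of a simulate block or input_dir", "config_error")
  st <- utils::modifyList(list(specificity = TRUE, ct_calling = TRUE,
                               conservation = TRUE, annotation = TRUE,
                               regulatory = TRUE, association = TRUE), stages)
  th <- utils::modifyList(list(min_frac = 0.01, k_sd = 3,
                               alpha_annotation = 0.01, alpha_exclusivity = 0.05,
                               spm_high = 0.9, spm_moderate = 0.6,
                               floor = NULL), thresholds)
  assert_that(is_fraction(th$min_frac), "threshold 'min_frac' must lie in [0,1]",
              "config_error")
  assert_that(th$k_sd > 0, "threshold 'k_sd' must be positive", "config_error")
  structure(list(simulate = simulate, input_dir = input_dir, outdir = outdir,
                 seed = seed, stages = st, thresholds = th),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a JSON file
#' @param path JSON file with the fields of [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(simulate = as.list(raw$simulate %||% list()),
                  input_dir = raw$input_dir,
                  outdir = raw$outdir %||% tempfile("ctlnc_run_"),
                  seed = raw$seed,
                  stages = as.list(raw$stages %||% list()),
                  thresholds = as.list(raw$thresholds %||% list()))
}

load_inputs <- function(config) {
  if (!is.null(config$input_dir)) {
    d <- config$input_dir
    fp <- function(f) file.path(d, f)
    tumors <- list.files(d, pattern = "^tumor_.*\\.tsv$", full.names = FALSE)
    cohorts <- lapply(tumors, function(f) read_expression(fp(f), "RPKM"))
    names(cohorts) <- sub("^tumor_(.*)\\.tsv$", "\\1", tumors)
    elements <- list()
    for (kind in c("promoter", "methylation", "enhancer")) {
      f <- fp(sprintf("elements_%s.bed", kind))
      if (file.exists(f)) elements[[kind]] <- read_bed6(f)
    }
    meth <- NULL
    if (file.exists(fp("methylation.tsv"))) {
      dt <- data.table::fread(fp("methylation.tsv"))
      meth <- as.matrix(dt[, -1, with = FALSE])
      rownames(meth) <- dt[[1]]
    }
    list(panel = read_expression(fp("normal_panel.tsv"), "RPKM"),
         tissues = data.table::fread(fp("tissue_labels.tsv")),
         cohorts = cohorts,
         genes = read_bed12(fp("genes.bed")),
         elements = elements,
         phastcons = read_bedgraph(fp("phastcons.bedGraph"), "phastcons"),
         phylop = read_bedgraph(fp("phylop.bedGraph"), "phylop"),
         gmt = read_gmt(fp("genesets.gmt")),
         maf = read_maf_lite(fp("mutations.maf.tsv")),
         clinical = read_clinical(fp("clinical.tsv")),
         methylation = meth,
         truth = if (file.exists(fp("truth.json"))) read_truth(fp("truth.json")))
  } else {
    args <- config$simulate
    if (!is.null(config$seed)) args$seed <- config$seed
    spec <- do.call(cohort_spec, args)
    sim <- simulate_cohort(spec)
    sim
  }
}

write_stage <- function(obj, path) {
  data.table::fwrite(data.table::as.data.table(obj), path, sep = "\t",
                     quote = FALSE, na = "NA")
  path
}

#' Run the full pipeline
#'
#' Stages run in dependency order on simulated or pre-generated inputs;
#' every output file is listed in `manifest.tsv` with its md5 hash.
#' Re-running with the same config and seed reproduces identical hashes.
#'
#' @param config a `pipeline_config` (or path to its JSON form).
#' @return list with `manifest` (data.table file, md5), `outdir`, and the
#'   in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  assert_that(inherits(config, "pipeline_config"),
              "config must be built with pipeline_config()", "config_error")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(config$outdir, f)
  th <- config$thresholds
  outputs <- character(0)
  emit <- function(obj, name) outputs <<- c(outputs, write_stage(obj, fp(name)))
  res <- list()

  inputs <- load_inputs(config)
  res$inputs <- inputs

  ## ---- specificity ----
  ts_genes <- character(0)
  if (config$stages$specificity) {
    lnc_models <- filter_lncrna_models(inputs$genes,
                                       inputs$genes[inputs$genes$biotype == "protein_coding", ])
    calls <- classify_testis_specific(inputs$panel, inputs$tissues,
                                      high = th$spm_high,
                                      moderate = th$spm_moderate)
    calls <- calls[calls$gene_id %in% lnc_models$gene_id, ]
    ts_genes <- calls$gene_id[calls$category == "TS_high_confidence"]
    res$specificity <- calls
    emit(calls, "ts_classification.tsv")
  }

  ## ---- CT / EECT calling ----
  act_counts <- NULL
  if (config$stages$ct_calling) {
    calls <- ct_call_table(inputs$cohorts, ts_genes, floor = th$floor,
                           min_frac = th$min_frac, k_sd = th$k_sd)
    res$ct_calls <- calls
    emit(calls, "ct_calls.tsv")
    act_list <- lapply(names(inputs$cohorts), function(type) {
      ee <- calls[calls$cancer_type == type, ]
      cbind(activation_counts(inputs$cohorts[[type]],
                              data.table::data.table(gene_id = ee$gene_id,
                                                     is_eect = ee$is_eect,
                                                     ee_threshold = ee$ee_threshold)),
            cancer_type = type)
    })
    act_counts <- data.table::rbindlist(act_list)
    res$activation_counts <- act_counts
    emit(act_counts, "activation_counts.tsv")
    eect_union <- unique(calls$gene_id[calls$is_eect])
    if (length(eect_union) >= 1) {
      comp <- composition_enrichment(eect_union, inputs$genes,
                                     background = inputs$genes$gene_id[
                                       grepl("^LNC", inputs$genes$gene_id)],
                                     stratifier = "biotype")
      res$composition_biotype <- comp
      emit(comp, "composition_biotype.tsv")
      compc <- composition_enrichment(eect_union, inputs$genes,
                                      background = inputs$genes$gene_id[
                                        grepl("^LNC", inputs$genes$gene_id)],
                                      stratifier = "chromosome")
      res$composition_chromosome <- compc
      emit(compc, "composition_chromosome.tsv")
    }
  }

  ## ---- conservation ----
  if (config$stages$conservation) {
    ct_union <- if (!is.null(res$ct_calls)) {
      unique(res$ct_calls$gene_id[res$ct_calls$is_ct])
    } else character(0)
    lnc_ids <- inputs$genes$gene_id[grepl("^LNC", inputs$genes$gene_id)]
    non_ts <- setdiff(lnc_ids, ts_genes)
    pick <- function(v, k = 100L) if (length(v) > k) v[seq_len(k)] else v
    use <- inputs$genes[inputs$genes$gene_id %in% c(pick(sort(ct_union)),
                                                    pick(sort(non_ts))), ]
    cons <- conservation_summary(use, inputs$phastcons, inputs$phylop)
    res$conservation <- cons
    emit(cons, "conservation_summary.tsv")
    ex <- cons[cons$region == "exons", ]
    grp_ct <- ex$mean_phastcons[ex$gene_id %in% ct_union]
    grp_non <- ex$mean_phastcons[!ex$gene_id %in% ct_union]
    if (length(grp_ct) && length(grp_non)) {
      w <- compare_groups(grp_ct, grp_non)
      cmp <- data.table::data.table(comparison = "ct_vs_nonts_exon_phastcons",
                                    statistic = w$statistic, p = w$p.value)
      res$conservation_test <- cmp
      emit(cmp, "conservation_comparison.tsv")
    }
  }

  ## ---- guilt-by-association annotation ----
  if (config$stages$annotation) {
    ct_union <- if (!is.null(res$ct_calls)) {
      unique(res$ct_calls$gene_id[res$ct_calls$is_ct])
    } else character(0)
    coexpr_mat <- inputs$cohorts[[1]]
    ann <- annotate_lncrna_set(coexpr_mat, ct_union, inputs$gmt,
                               floor = th$floor, min_frac = th$min_frac,
                               alpha = th$alpha_annotation)
    res$annotation <- ann
    ann_tab <- data.table::data.table(
      lncrna = rep(names(ann$annotations), lengths(ann$annotations)),
      term = unlist(ann$annotations, use.names = FALSE))
    emit(ann_tab, "lncrna_annotations.tsv")
    if (length(intersect(ct_union, ann$expanded_db$universe))) {
      cte <- ct_set_enrichment(ct_union, ann$expanded_db)
      res$ct_set_enrichment <- cte
      emit(cte, "ct_set_enrichment.tsv")
    }
  }

  ## ---- regulatory-element windows ----
  if (config$stages$regulatory && length(inputs$elements)) {
    lnc_ids <- inputs$genes$gene_id[grepl("^LNC", inputs$genes$gene_id)]
    background <- setdiff(lnc_ids, ts_genes)
    kinds <- list(promoter = "promoter_window", methylation = "methylation_window",
                  enhancer = "enhancer_flanks")
    reg_rows <- list()
    for (kind in names(inputs$elements)) {
      if (length(ts_genes) == 0 || length(background) == 0) break
      we <- window_enrichment(inputs$genes, ts_genes, background,
                              inputs$elements[[kind]],
                              window_spec(kinds[[kind]]))
      reg_rows[[kind]] <- data.table::data.table(
        element_type = kind,
        n_target_with = we$table[1, 1], n_target = length(ts_genes),
        n_background_with = we$table[2, 1],
        n_background = length(background),
        odds_ratio = we$odds.ratio, odds_ratio_haldane = we$odds.ratio.haldane,
        p = we$p.value)
    }
    if (length(reg_rows)) {
      reg <- data.table::rbindlist(reg_rows)
      res$regulatory <- reg
      emit(reg, "window_enrichment.tsv")
    }
  }

  ## ---- association models ----
  if (config$stages$association && !is.null(act_counts) &&
      !is.null(inputs$clinical)) {
    fit <- tryCatch(stage_association(act_counts, inputs$clinical),
                    ctlnc_error = function(e) NULL)
    if (!is.null(fit)) {
      res$stage_fit <- fit
      emit(fit$terms, "stage_fit.tsv")
    }
    if (!is.null(inputs$methylation) && nrow(inputs$methylation) > 0) {
      mean_beta <- colMeans(inputs$methylation)[act_counts$sample_id]
      mfit <- tryCatch(
        methylation_association(mean_beta, act_counts,
                                cancer_type = act_counts$cancer_type),
        ctlnc_error = function(e) NULL)
      if (!is.null(mfit)) {
        res$methylation_fit <- mfit
        emit(mfit$terms, "methylation_fit.tsv")
      }
    }
    if (!is.null(inputs$maf) && nrow(inputs$maf) > 0) {
      mutated <- unique(inputs$maf$sample_id)
      grp <- ifelse(act_counts$sample_id %in% mutated, "positive", "negative")
      if (length(unique(grp)) == 2) {
        og <- oncogene_group_test(act_counts$n_activated_eect, grp)
        ogt <- data.table::data.table(test = "oncogene_positive_vs_negative",
                                      statistic = og$statistic, p = og$p.value)
        res$oncogene_test <- ogt
        emit(ogt, "oncogene_test.tsv")
      }
      # per-cancer-type exclusivity screen on the first cohort
      type <- names(inputs$cohorts)[1]
      ee <- res$ct_calls[res$ct_calls$cancer_type == type & res$ct_calls$is_eect, ]
      if (nrow(ee) > 0) {
        amat <- activation_matrix(inputs$cohorts[[type]],
                                  data.table::data.table(gene_id = ee$gene_id,
                                                         is_eect = TRUE,
                                                         ee_threshold = ee$ee_threshold))
        samples <- colnames(inputs$cohorts[[type]])
        drivers <- sort(unique(inputs$maf$gene))
        mmat <- vapply(drivers, function(d)
          samples %in% inputs$maf$sample_id[inputs$maf$gene == d],
          logical(length(samples)))
        rownames(mmat) <- samples
        scr <- mutual_exclusivity_screen(amat, mmat,
                                         alpha = th$alpha_exclusivity)
        res$exclusivity <- scr
        emit(scr$results, "exclusivity_screen.tsv")
      }
    }
  }

  manifest <- data.table::data.table(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs))
  )
  data.table::setorder(manifest, file)
  write_stage(manifest, fp("manifest.tsv"))
  res$manifest <- manifest
  res$outdir <- config$outdir
  res
}
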