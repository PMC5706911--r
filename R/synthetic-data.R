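# Synthetic-cohort generator with planted ground truth.
#
# The generator emulates the statistical structure the pipeline consumes:
# a multi-tissue normal panel (testis included), per-cancer tumor cohorts in
# which a planted subset of testis-specific lncRNAs is sparsely reactivated
# at a large log2 effect, co-expression modules tied to gene sets, regulatory
# elements placed in the strand-aware flanking windows of target genes,
# promoter hypo-methylation coupled to activation, and driver mutations
# mutually exclusive with activation. Everything is a pure function of
# (spec, seed): sub-generators derive child seeds by fixed offsets.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators do not disturb
#' user code.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rbeta_mean <- function(n, mean, conc = 30) {
  mean <- pmin(pmax(mean, 0.02), 0.98)
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Specification of a synthetic cohort
#'
#' Defaults describe the stated world every recovery test runs against:
#' 24 normal tissues (testis included) with 30 individuals each, two tumor
#' cohorts of 200 samples, 1,500 genes of which 500 are lncRNAs, 30% of
#' lncRNAs planted testis-specific, 60% of those reactivated in tumors with
#' a 6 log2-unit activation effect in 5% of samples, and five 20-gene
#' co-expression modules (5 lncRNAs + 15 coding genes each) at a within-
#' module Spearman correlation of 0.8, each tied to one gene-set term.
#'
#' @param n_tissues number of normal tissues (one must be testis).
#' @param n_normal_individuals individuals per normal tissue.
#' @param n_tumor_samples_per_type tumor cohort size per cancer type.
#' @param cancer_types character vector of cohort labels.
#' @param n_genes total genes (coding + lncRNA).
#' @param n_lncrna number of lncRNAs among `n_genes`.
#' @param frac_ts fraction of lncRNAs planted testis-specific.
#' @param frac_ct_of_ts fraction of TS lncRNAs planted tumor-reactivated.
#' @param activation_frequency per-gene fraction of tumor samples activated.
#' @param activation_log2_effect mean log2 expression of activated samples.
#' @param baseline_log2_mean,baseline_log2_sd background log2 expression.
#' @param dropout_rate fraction of exact zeros in broadly expressed genes.
#' @param n_modules,module_size,module_lnc co-expression module layout.
#' @param rho_within target within-module Spearman correlation.
#' @param seed global integer seed.
#' @param unit expression unit dialect of the emitted matrices.
#' @param ts_testis_log2_shift testis log2 shift of TS genes over baseline.
#' @param ts_leak_rate,broad_log2_mean,broad_log2_sd nuisance expression
#'   parameters (leaky TS expression outside testis; broadly re-expressed
#'   CT module genes in tumors).
#' @param frac_ts_coding fraction of coding genes planted testis-specific.
#' @param coupling_rho_no_enh,coupling_rho_enh testis Spearman coupling of a
#'   TS lncRNA with its nearest TS coding gene, without/with a planted
#'   enhancer nearby.
#' @param element_target_frac fraction of TS lncRNAs receiving each planted
#'   regulatory element type.
#' @param n_background_elements background elements per type, placed away
#'   from all gene windows.
#' @param n_terms,decoy_term_size gene-set collection layout (planted terms
#'   are exactly the module coding genes).
#' @param methylation_effect_size mean drop in promoter beta of activated
#'   samples.
#' @param stage_effect relative increase of activation probability per AJCC
#'   stage unit.
#' @param n_drivers,driver_mutation_rate,n_exclusive_pairs mutation design.
#' @param cons_low,cons_high Beta means of the PhastCons distribution for
#'   CT-gene regions versus everything else.
#' @return validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_tissues = 24L,
                        n_normal_individuals = 30L,
                        n_tumor_samples_per_type = 200L,
                        cancer_types = c("CANCER_A", "CANCER_B"),
                        n_genes = 1500L,
                        n_lncrna = 500L,
                        frac_ts = 0.3,
                        frac_ct_of_ts = 0.6,
                        activation_frequency = 0.05,
                        activation_log2_effect = 6,
                        baseline_log2_mean = 3,
                        baseline_log2_sd = 1,
                        dropout_rate = 0.05,
                        n_modules = 5L,
                        module_size = 20L,
                        module_lnc = 5L,
                        rho_within = 0.8,
                        seed = 1L,
                        unit = "RPKM",
                        ts_testis_log2_shift = 3,
                        ts_leak_rate = 0.02,
                        broad_log2_mean = 2,
                        broad_log2_sd = 1,
                        frac_ts_coding = 0.1,
                        coupling_rho_no_enh = 0.8,
                        coupling_rho_enh = 0.2,
                        element_target_frac = 0.5,
                        n_background_elements = 100L,
                        n_terms = 50L,
                        decoy_term_size = 40L,
                        methylation_effect_size = 0.3,
                        stage_effect = 0.5,
                        n_drivers = 5L,
                        driver_mutation_rate = 0.3,
                        n_exclusive_pairs = 3L,
                        cons_low = 0.2,
                        cons_high = 0.8) {
  spec <- as.list(environment())
  counts <- c("n_tissues", "n_normal_individuals", "n_tumor_samples_per_type",
              "n_genes", "n_lncrna", "n_modules", "module_size", "module_lnc",
              "n_terms", "decoy_term_size", "n_drivers")
  for (f in counts) {
    assert_that(is_count(spec[[f]]), "cohort_spec field '%s' must be a positive integer",
                "config_error", f)
  }
  fracs <- c("frac_ts", "frac_ct_of_ts", "activation_frequency", "dropout_rate",
             "ts_leak_rate", "frac_ts_coding", "element_target_frac",
             "driver_mutation_rate", "methylation_effect_size",
             "cons_low", "cons_high", "rho_within",
             "coupling_rho_no_enh", "coupling_rho_enh")
  for (f in fracs) {
    assert_that(is_fraction(spec[[f]]), "cohort_spec field '%s' must lie in [0, 1]",
                "config_error", f)
  }
  assert_that(spec$activation_log2_effect > 0,
              "cohort_spec field 'activation_log2_effect' must be > 0", "config_error")
  assert_that(spec$n_lncrna < spec$n_genes,
              "cohort_spec field 'n_lncrna' must be smaller than 'n_genes'", "config_error")
  assert_that(length(spec$cancer_types) >= 1 && !anyDuplicated(spec$cancer_types),
              "cohort_spec field 'cancer_types' must be distinct labels", "config_error")
  assert_that(spec$module_lnc < spec$module_size,
              "cohort_spec field 'module_lnc' must be smaller than 'module_size'",
              "config_error")
  assert_that(spec$n_tissues >= 2,
              "cohort_spec field 'n_tissues' must be at least 2", "config_error")
  assert_that(is_count(spec$seed %||% 0) || (is.numeric(spec$seed) && spec$seed == 0),
              "cohort_spec field 'seed' must be an integer", "config_error")
  assert_that(spec$unit %in% c("RPKM", "normalized_read_counts"),
              "cohort_spec field 'unit' must be RPKM or normalized_read_counts",
              "config_error")
  assert_that(spec$n_exclusive_pairs >= 0,
              "cohort_spec field 'n_exclusive_pairs' must be >= 0", "config_error")
  spec$tissues <- c("testis", sprintf("tissue%02d", seq_len(spec$n_tissues - 1) + 1L))
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d genes (%d lncRNA), %d tissues x %d, %s x %d tumor samples, seed %d\n",
              x$n_genes, x$n_lncrna, x$n_tissues, x$n_normal_individuals,
              paste(x$cancer_types, collapse = "/"), x$n_tumor_samples_per_type,
              x$seed))
  invisible(x)
}

spec_signature <- function(spec) {
  list(seed = spec$seed, n_genes = spec$n_genes, n_lncrna = spec$n_lncrna,
       cancer_types = spec$cancer_types,
       n_tumor_samples_per_type = spec$n_tumor_samples_per_type)
}

validate_truth <- function(spec, truth) {
  assert_that(identical(truth$spec_signature, spec_signature(spec)),
              "truth was generated from a different cohort_spec", "consistency_error")
  invisible(TRUE)
}

#' Deterministic genomic layout of the synthetic genes
#'
#' One chromosome per 500 genes; genes placed on alternating strands with a
#' 65 kb start spacing so the 20 kb/5 kb flanking windows of adjacent genes
#' can never collide. Pure function of the spec seed.
#'
#' @param spec a `cohort_spec`.
#' @return a `gene_models` table for all genes.
#' @export
gene_layout <- function(spec) {
  with_seed(child_seed(spec$seed, 11L), {
    n_cod <- spec$n_genes - spec$n_lncrna
    ids <- c(sprintf("LNC%04d", seq_len(spec$n_lncrna)),
             sprintf("PC%04d", seq_len(n_cod)))
    biotype <- c(sample(c("lincRNA", "antisense", "processed_transcript"),
                        spec$n_lncrna, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
                 rep("protein_coding", n_cod))
    ord <- sample(spec$n_genes)           # interleave lncRNAs and coding genes
    ids <- ids[ord]; biotype <- biotype[ord]
    per_chrom <- 500L
    chrom_idx <- ((seq_len(spec$n_genes) - 1L) %/% per_chrom) + 1L
    within <- ((seq_len(spec$n_genes) - 1L) %% per_chrom) + 1L
    start <- 50000L + (within - 1L) * 65000L
    len <- sample(1000:5000, spec$n_genes, replace = TRUE)
    strand <- rep_len(c("+", "-"), spec$n_genes)
    exs <- vector("list", spec$n_genes)
    exe <- vector("list", spec$n_genes)
    for (i in seq_len(spec$n_genes)) {
      n_ex <- sample(1:3, 1)
      if (n_ex == 1) {
        exs[[i]] <- start[i]; exe[[i]] <- start[i] + len[i]
      } else {
        m <- 2L * n_ex - 1L
        w <- stats::runif(m, 0.2, 1)
        b <- start[i] + round(cumsum(w) / sum(w) * len[i])
        b <- c(start[i], b[-m], start[i] + len[i])
        seg_s <- b[-length(b)]; seg_e <- b[-1]
        keep <- seq(1, m, by = 2)
        exs[[i]] <- as.integer(seg_s[keep]); exe[[i]] <- as.integer(seg_e[keep])
      }
    }
    gene_models(data.table::data.table(
      gene_id = ids,
      chrom = sprintf("chr%d", chrom_idx),
      start = as.integer(start),
      end = as.integer(start + len),
      strand = strand,
      biotype = biotype,
      exons_start = exs,
      exons_end = exe
    ))
  })
}

# Nearest TS coding gene (same chromosome, distance between spans) per TS
# lncRNA; NA when the chromosome carries no TS coding gene.
nearest_ts_coding <- function(layout, ts_lnc, ts_coding) {
  if (length(ts_lnc) == 0 || length(ts_coding) == 0) {
    return(data.table::data.table(lncrna = character(0), coding = character(0)))
  }
  ld <- layout[layout$gene_id %in% ts_lnc, ]
  cd <- layout[layout$gene_id %in% ts_coding, ]
  res <- lapply(seq_len(nrow(ld)), function(i) {
    cand <- cd[cd$chrom == ld$chrom[i], ]
    if (nrow(cand) == 0) return(NULL)
    d <- pmax(0, pmax(cand$start - ld$end[i], ld$start[i] - cand$end))
    data.table::data.table(lncrna = ld$gene_id[i],
                           coding = cand$gene_id[which.min(d)],
                           distance = min(d))
  })
  data.table::rbindlist(res)
}

#' Generate the multi-tissue normal panel and the planted truth
#'
#' Samples are `n_tissues x n_normal_individuals`. Planted TS genes are
#' expressed in testis (baseline + `ts_testis_log2_shift` on log2 scale) and
#' only leak rarely elsewhere; all other genes are broadly expressed. The
#' truth object fixes the TS/CT/EECT nesting, module memberships, the
#' regulatory-element placement plan and the driver-exclusivity pairs used
#' by the later generators.
#'
#' @param spec a `cohort_spec`.
#' @return list with `panel` (an `expr_matrix`), `tissues` (sample_id ->
#'   tissue table) and `truth` (a `synthetic_truth` list).
#' @export
generate_normal_panel <- function(spec) {
  assert_that(inherits(spec, "cohort_spec"),
              "spec must be built with cohort_spec()", "config_error")
  layout <- gene_layout(spec)
  lnc_ids <- grep("^LNC", layout$gene_id, value = TRUE)
  cod_ids <- grep("^PC", layout$gene_id, value = TRUE)

  with_seed(child_seed(spec$seed, 21L), {
    ## ---- planted truth ----
    n_ts <- round(spec$frac_ts * spec$n_lncrna)
    ts_genes <- sort(sample(lnc_ids, n_ts))
    n_ct <- round(spec$frac_ct_of_ts * n_ts)
    ct_genes <- sort(sample(ts_genes, n_ct))
    ts_coding <- sort(sample(cod_ids, round(spec$frac_ts_coding * length(cod_ids))))

    # co-expression modules: lncRNA members drawn from CT genes when there
    # are enough, topped up from non-TS lncRNAs (they must be broadly
    # expressed in tumors for co-expression to exist)
    need_lnc <- spec$n_modules * spec$module_lnc
    pool <- c(sample(ct_genes), sample(setdiff(lnc_ids, ts_genes)))
    assert_that(need_lnc <= length(pool),
                "not enough lncRNAs for the requested modules", "config_error")
    mod_lnc <- pool[seq_len(need_lnc)]
    cod_per_mod <- spec$module_size - spec$module_lnc
    cod_pool <- sample(setdiff(cod_ids, ts_coding))
    assert_that(spec$n_modules * cod_per_mod <= length(cod_pool),
                "not enough coding genes for the requested modules", "config_error")
    mod_cod <- cod_pool[seq_len(spec$n_modules * cod_per_mod)]
    module_ids <- sprintf("M%d", seq_len(spec$n_modules))
    module_assignment <- c(
      stats::setNames(rep(module_ids, each = spec$module_lnc), mod_lnc),
      stats::setNames(rep(module_ids, each = cod_per_mod), mod_cod)
    )
    eect_genes <- sort(setdiff(ct_genes, mod_lnc))

    ## ---- regulatory-element placement plan ----
    pick_targets <- function(prefix) {
      k <- round(spec$element_target_frac * length(ts_genes))
      if (k == 0) return(character(0))
      stats::setNames(sort(sample(ts_genes, k)), NULL)
    }
    plan <- list(promoter = pick_targets(), methylation = pick_targets(),
                 enhancer = pick_targets())
    element_placements <- c(
      stats::setNames(plan$promoter, sprintf("PROM_%s", plan$promoter)),
      stats::setNames(plan$methylation, sprintf("METH_%s", plan$methylation)),
      stats::setNames(plan$enhancer, sprintf("ENH_%s", plan$enhancer))
    )

    ## ---- exclusivity pairs ----
    n_pairs <- min(spec$n_exclusive_pairs, spec$n_drivers, length(eect_genes))
    exclusive_pairs <- if (n_pairs > 0) {
      data.table::data.table(driver = sprintf("DRV%d", seq_len(n_pairs)),
                             lncrna = sample(eect_genes, n_pairs))
    } else {
      data.table::data.table(driver = character(0), lncrna = character(0))
    }

    methylation_effect <- if (spec$methylation_effect_size > 0 && length(eect_genes)) {
      stats::setNames(rep(-1L, length(eect_genes)), eect_genes)
    } else {
      stats::setNames(integer(0), character(0))
    }

    pairs <- nearest_ts_coding(layout, ts_genes, ts_coding)
    if (nrow(pairs)) pairs$enhancer <- pairs$lncrna %in% plan$enhancer

    ## ---- expression ----
    samples <- as.vector(vapply(spec$tissues, function(t)
      sprintf("N_%s_%02d", t, seq_len(spec$n_normal_individuals)),
      character(spec$n_normal_individuals)))
    tissue_of <- rep(spec$tissues, each = spec$n_normal_individuals)
    n_s <- length(samples)
    is_testis <- tissue_of == "testis"

    log2x <- matrix(stats::rnorm(spec$n_genes * n_s, spec$baseline_log2_mean,
                                 spec$baseline_log2_sd),
                    spec$n_genes, n_s, dimnames = list(layout$gene_id, samples))
    vals <- 2^log2x
    if (spec$dropout_rate > 0) {
      vals[matrix(stats::runif(length(vals)) < spec$dropout_rate,
                  nrow(vals), ncol(vals))] <- 0
    }

    ts_all <- c(ts_genes, ts_coding)
    if (length(ts_all)) {
      # outside testis: zero with rare low-level leak
      leak <- matrix(0, length(ts_all), sum(!is_testis))
      nz <- stats::runif(length(leak)) < spec$ts_leak_rate
      leak[nz] <- 2^stats::rnorm(sum(nz), -2, 0.5)
      vals[ts_all, !is_testis] <- leak
      # testis: high expression
      z_ts <- matrix(stats::rnorm(length(ts_all) * sum(is_testis)),
                     length(ts_all), sum(is_testis),
                     dimnames = list(ts_all, NULL))
      # couple each TS lncRNA to its nearest TS coding gene in testis
      if (nrow(pairs)) {
        for (i in seq_len(nrow(pairs))) {
          r <- 2 * sin(pi * (if (pairs$enhancer[i]) spec$coupling_rho_enh
                             else spec$coupling_rho_no_enh) / 6)
          z_ts[pairs$lncrna[i], ] <- r * z_ts[pairs$coding[i], ] +
            sqrt(1 - r^2) * stats::rnorm(sum(is_testis))
        }
      }
      mu <- spec$baseline_log2_mean + spec$ts_testis_log2_shift
      vals[ts_all, is_testis] <- 2^(mu + spec$baseline_log2_sd * z_ts)
    }

    truth <- structure(list(
      ts_genes = ts_genes,
      ct_genes = ct_genes,
      eect_genes = eect_genes,
      module_assignment = module_assignment,
      element_placements = element_placements,
      methylation_effect = methylation_effect,
      exclusive_pairs = exclusive_pairs,
      ts_coding = ts_coding,
      testis_pairs = pairs,
      module_lnc = mod_lnc,
      spec_signature = spec_signature(spec)
    ), class = "synthetic_truth")

    list(panel = expression_matrix(vals, spec$unit),
         tissues = data.table::data.table(sample_id = samples, tissue = tissue_of),
         truth = truth)
  })
}

#' Generate per-cancer tumor cohorts
#'
#' Planted EECT genes are activated in a stage-dependent Bernoulli subset of
#' samples with a `activation_log2_effect` log2 shift (activation probability
#' is forced to zero in samples carrying the paired driver mutation);
#' CT module genes are broadly re-expressed and share a latent factor giving
#' within-module Spearman correlation near `rho_within`; never-reactivated TS
#' genes stay below the expression floor. The joint latent design (clinical
#' covariates, driver mutations, per-sample activation) is stashed in the
#' returned truth for [generate_methylation_mutations_clinical()].
#'
#' @param spec a `cohort_spec`.
#' @param truth truth from [generate_normal_panel()] under the same spec.
#' @return list with `cohorts` (named list of `expr_matrix`) and the updated
#'   `truth`.
#' @export
generate_tumor_cohorts <- function(spec, truth) {
  validate_truth(spec, truth)
  layout <- gene_layout(spec)
  lnc_ids <- grep("^LNC", layout$gene_id, value = TRUE)
  r_mod <- 2 * sin(pi * spec$rho_within / 6)   # Gaussian-copula latent r
  drivers <- sprintf("DRV%d", seq_len(spec$n_drivers))

  mod_members <- names(truth$module_assignment)
  broad_lnc <- truth$module_lnc                          # CT but not extreme
  sparse_ts <- setdiff(truth$ts_genes, truth$ct_genes)   # never reactivated
  other_lnc <- setdiff(lnc_ids, c(truth$ts_genes, mod_members))
  cod_ids <- grep("^PC", layout$gene_id, value = TRUE)
  plain_cod <- setdiff(cod_ids, c(mod_members, truth$ts_coding))

  cohorts <- list()
  stash <- list()
  for (ti in seq_along(spec$cancer_types)) {
    type <- spec$cancer_types[ti]
    cohorts[[type]] <- with_seed(child_seed(spec$seed, 31L + ti), {
      n_s <- spec$n_tumor_samples_per_type
      samples <- sprintf("T_%s_%03d", type, seq_len(n_s))

      clinical <- data.table::data.table(
        sample_id = samples,
        age = pmin(90L, pmax(30L, round(stats::rnorm(n_s, 65, 10)))),
        gender = sample(c("male", "female"), n_s, replace = TRUE),
        stage = sample(1:4, n_s, replace = TRUE, prob = c(0.3, 0.3, 0.25, 0.15)),
        cancer_type = type
      )

      mut <- matrix(stats::runif(n_s * spec$n_drivers) < spec$driver_mutation_rate,
                    n_s, spec$n_drivers, dimnames = list(samples, drivers))

      # stage-coupled activation probability, exclusivity-aware
      act <- matrix(FALSE, length(truth$eect_genes), n_s,
                    dimnames = list(truth$eect_genes, samples))
      if (length(truth$eect_genes)) {
        p_base <- spec$activation_frequency *
          (1 + spec$stage_effect * (clinical$stage - 2.5))
        p_base <- pmin(pmax(p_base, 0), 1)
        for (g in truth$eect_genes) {
          p <- p_base
          hit <- truth$exclusive_pairs$lncrna == g
          if (any(hit)) {
            d <- truth$exclusive_pairs$driver[hit][1]
            p[mut[, d]] <- 0
          }
          act[g, ] <- stats::runif(n_s) < p
        }
      }

      vals <- matrix(0, spec$n_genes, n_s,
                     dimnames = list(layout$gene_id, samples))
      fill_broad <- function(ids, mu, sd, dropout = spec$dropout_rate) {
        if (!length(ids)) return()
        m <- 2^matrix(stats::rnorm(length(ids) * n_s, mu, sd), length(ids), n_s)
        if (dropout > 0) {
          m[matrix(stats::runif(length(m)) < dropout, nrow(m), ncol(m))] <- 0
        }
        vals[ids, ] <<- m
      }
      fill_leak <- function(ids) {
        if (!length(ids)) return()
        m <- matrix(0, length(ids), n_s)
        nz <- stats::runif(length(m)) < spec$ts_leak_rate
        m[nz] <- 2^stats::rnorm(sum(nz), -4.5, 0.3)   # stays below the floor
        vals[ids, ] <<- m
      }
      fill_broad(plain_cod, spec$baseline_log2_mean, spec$baseline_log2_sd)
      fill_broad(other_lnc, spec$baseline_log2_mean - 1, spec$baseline_log2_sd)
      fill_leak(sparse_ts)
      fill_leak(truth$ts_coding)

      # module members: shared latent factor, no dropout (dropout would
      # erode the planted rank correlation)
      for (mid in unique(truth$module_assignment)) {
        ids <- names(truth$module_assignment)[truth$module_assignment == mid]
        f <- stats::rnorm(n_s)
        z <- r_mod * matrix(f, length(ids), n_s, byrow = TRUE) +
          sqrt(1 - r_mod^2) * matrix(stats::rnorm(length(ids) * n_s),
                                     length(ids), n_s)
        mu <- ifelse(grepl("^LNC", ids), spec$broad_log2_mean,
                     spec$baseline_log2_mean)
        vals[ids, ] <- 2^(mu + spec$broad_log2_sd * z)
      }

      # extreme activation on top of leak background
      if (length(truth$eect_genes)) {
        leak <- matrix(0, length(truth$eect_genes), n_s,
                       dimnames = list(truth$eect_genes, samples))
        nz <- stats::runif(length(leak)) < spec$ts_leak_rate
        leak[nz] <- 2^stats::rnorm(sum(nz), -4.5, 0.3)
        hot <- 2^matrix(stats::rnorm(length(leak), spec$activation_log2_effect,
                                     spec$baseline_log2_sd),
                        nrow(leak), ncol(leak))
        leak[act] <- hot[act]
        vals[truth$eect_genes, ] <- leak
      }

      stash[[type]] <- list(clinical = clinical, mutations = mut,
                            activated = act)
      expression_matrix(vals, spec$unit)
    })
  }
  truth$tumor <- stash
  list(cohorts = cohorts, truth = truth)
}

bin_intervals <- function(start, end, width = 200L) {
  nb <- pmax(1L, as.integer(ceiling((end - start) / width)))
  s <- rep(start, nb) + (sequence(nb) - 1L) * width
  e <- pmin(s + width, rep(end, nb))
  list(start = as.integer(s), end = as.integer(e), owner = rep(seq_along(start), nb))
}

#' Generate gene models, regulatory-element catalogs, conservation tracks
#' and the gene-set collection
#'
#' Planted promoter elements fall 100 bp-5 kb upstream of their target gene
#' (strand-aware), methylation sites 100 bp-1 kb upstream, enhancers within
#' 20 kb upstream or 5 kb downstream; background elements are placed
#' uniformly at least 30 kb away from every gene span, hence outside every
#' window. Conservation tracks cover the exon-promoter union of each gene:
#' CT-gene regions are drawn from a lower-conservation distribution.
#'
#' @param spec a `cohort_spec`.
#' @param truth truth from [generate_normal_panel()].
#' @return list with `genes`, `elements` (named list of BED6 tables per
#'   type), `phastcons`, `phylop`, `gmt`, `planted_terms` and the updated
#'   `truth` (background element ids appended to the placement map).
#' @export
generate_annotation <- function(spec, truth) {
  validate_truth(spec, truth)
  layout <- gene_layout(spec)
  idx <- stats::setNames(seq_len(nrow(layout)), layout$gene_id)

  with_seed(child_seed(spec$seed, 41L), {
    widths <- c(promoter = 200L, methylation = 2L, enhancer = 500L)
    prefix <- c(promoter = "PROM", methylation = "METH", enhancer = "ENH")
    place_planted <- function(kind, target) {
      g <- layout[idx[target], ]
      w <- widths[[kind]]
      fwd <- g$strand == "+"
      if (kind == "enhancer") {
        up <- stats::runif(1) < 0.7
        if (up) {
          lo <- if (fwd) g$start - 20000L else g$end
          hi <- if (fwd) g$start - w else g$end + 20000L - w
        } else {
          lo <- if (fwd) g$end else g$start - 5000L
          hi <- if (fwd) g$end + 5000L - w else g$start - w
        }
      } else {
        far <- if (kind == "promoter") 5000L else 1000L
        lo <- if (fwd) g$start - far else g$end + 100L
        hi <- if (fwd) g$start - 100L - w else g$end + far - w
      }
      s <- sample(seq(max(0L, lo), hi), 1)
      data.table::data.table(chrom = g$chrom, start = as.integer(s),
                             end = as.integer(s + w),
                             name = sprintf("%s_%s", prefix[[kind]], target),
                             score = 0, strand = NA_character_)
    }

    # background elements: uniform over the intergenic space at least 26 kb
    # from every gene span (no flanking window reaches further than 20 kb
    # plus the element width, so these can never fall inside a window)
    chrom_len <- layout[, list(len = max(end) + 150000L), by = "chrom"]
    gr_genes <- genes_to_granges(layout)
    GenomicRanges::strand(gr_genes) <- "*"
    GenomeInfoDb::seqlevels(gr_genes) <- chrom_len$chrom
    GenomeInfoDb::seqlengths(gr_genes) <- chrom_len$len
    forbidden <- GenomicRanges::reduce(gr_genes + 26000L)
    allowed <- GenomicRanges::gaps(forbidden)
    allowed <- allowed[GenomicRanges::strand(allowed) == "*"]
    place_background <- function(kind, i) {
      w <- widths[[kind]]
      ok <- allowed[GenomicRanges::width(allowed) >= w + 2L]
      wt <- GenomicRanges::width(ok) - w - 1L
      ri <- sample(length(ok), 1, prob = wt)
      s <- GenomicRanges::start(ok)[ri] - 1L + sample(wt[ri], 1)
      data.table::data.table(
        chrom = as.character(GenomicRanges::seqnames(ok))[ri],
        start = as.integer(s), end = as.integer(s + w),
        name = sprintf("BG_%s_%03d", prefix[[kind]], i),
        score = 0, strand = NA_character_)
    }

    elements <- list()
    bg_ids <- character(0)
    for (kind in c("promoter", "methylation", "enhancer")) {
      pref <- sprintf("%s_", prefix[[kind]])
      planted <- names(truth$element_placements)[startsWith(names(truth$element_placements), pref)]
      rows <- lapply(planted, function(el)
        place_planted(kind, truth$element_placements[[el]]))
      bg <- lapply(seq_len(spec$n_background_elements), function(i)
        place_background(kind, i))
      elements[[kind]] <- data.table::rbindlist(c(rows, bg))
      bg_ids <- c(bg_ids, vapply(bg, function(x) x$name, character(1)))
    }
    truth$element_placements <- c(
      truth$element_placements,
      stats::setNames(rep("background", length(bg_ids)), bg_ids)
    )

    # conservation tracks over exon-promoter unions, 200 bp bins
    low <- layout$gene_id %in% truth$ct_genes
    n_ex <- lengths(layout$exons_start)
    prom_s <- ifelse(layout$strand == "+", pmax(0L, layout$start - 2000L),
                     pmax(0L, layout$end - 500L))
    prom_e <- ifelse(layout$strand == "+", layout$start + 500L,
                     layout$end + 2000L)
    iv_gene <- c(rep(seq_len(nrow(layout)), n_ex), seq_len(nrow(layout)))
    ir <- IRanges::IRanges(
      start = c(unlist(layout$exons_start), prom_s) + 1L,
      end = c(unlist(layout$exons_end), prom_e))
    red <- IRanges::reduce(S4Vectors::split(ir, iv_gene))
    per_gene <- lengths(red)
    flat <- unlist(red, use.names = FALSE)
    owner_gene <- rep(as.integer(names(red)), per_gene)
    b <- bin_intervals(IRanges::start(flat) - 1L, IRanges::end(flat))
    bin_gene <- owner_gene[b$owner]
    nb <- length(b$start)
    cons_mean <- ifelse(low[bin_gene], spec$cons_low, spec$cons_high)
    ph_rows <- data.table::data.table(
      chrom = layout$chrom[bin_gene], start = b$start, end = b$end,
      value = round(rbeta_mean(nb, cons_mean, 10), 4))
    py_rows <- data.table::data.table(
      chrom = layout$chrom[bin_gene], start = b$start, end = b$end,
      value = round(stats::rnorm(nb, ifelse(low[bin_gene], -1, 2), 1), 4))

    # gene sets: planted terms are exactly the module coding genes
    cod_ids <- grep("^PC", layout$gene_id, value = TRUE)
    mods <- unique(truth$module_assignment)
    gmt <- list()
    planted_terms <- character(0)
    for (mid in mods) {
      members <- names(truth$module_assignment)[truth$module_assignment == mid]
      term <- sprintf("TERM_%s", mid)
      gmt[[term]] <- sort(grep("^PC", members, value = TRUE))
      planted_terms[mid] <- term
    }
    non_mod <- setdiff(cod_ids, names(truth$module_assignment))
    n_decoys <- max(0L, spec$n_terms - length(mods))
    for (i in seq_len(n_decoys)) {
      gmt[[sprintf("TERM_D%02d", i)]] <-
        sort(sample(non_mod, min(spec$decoy_term_size, length(non_mod))))
    }
    truth$planted_terms <- planted_terms

    list(genes = layout,
         elements = elements,
         phastcons = score_track(ph_rows, "phastcons"),
         phylop = score_track(py_rows, "phylop"),
         gmt = gmt,
         truth = truth)
  })
}

#' Generate the methylation matrix, MAF-lite mutation table and clinical table
#'
#' Promoter beta values of activated samples are shifted down by
#' `methylation_effect_size`; the mutation table realizes the driver carriers
#' drawn (exclusivity-aware) during tumor generation; the clinical table
#' carries the stage values that drove the activation trend.
#'
#' @param spec a `cohort_spec`.
#' @param truth truth updated by [generate_tumor_cohorts()].
#' @return list with `methylation` (probes x samples matrix of beta values),
#'   `maf` and `clinical` tables.
#' @export
generate_methylation_mutations_clinical <- function(spec, truth) {
  validate_truth(spec, truth)
  assert_that(!is.null(truth$tumor),
              "tumor cohorts must be generated before methylation/mutations/clinical",
              "consistency_error")
  with_seed(child_seed(spec$seed, 51L), {
    clin <- data.table::rbindlist(lapply(truth$tumor, `[[`, "clinical"))
    clin$stage <- c("I", "II", "III", "IV")[clin$stage]

    maf_rows <- list()
    for (type in names(truth$tumor)) {
      mut <- truth$tumor[[type]]$mutations
      hit <- which(mut, arr.ind = TRUE)
      if (nrow(hit)) {
        maf_rows[[type]] <- data.table::data.table(
          sample_id = rownames(mut)[hit[, 1]],
          gene = colnames(mut)[hit[, 2]],
          variant_class = sample(c("Missense_Mutation", "Nonsense_Mutation"),
                                 nrow(hit), replace = TRUE, prob = c(0.8, 0.2)))
      }
    }
    maf <- if (length(maf_rows)) data.table::rbindlist(maf_rows) else {
      data.table::data.table(sample_id = character(0), gene = character(0),
                             variant_class = character(0))
    }
    data.table::setorder(maf, sample_id, gene)

    genes <- truth$eect_genes
    all_samples <- unlist(lapply(truth$tumor, function(s) s$clinical$sample_id),
                          use.names = FALSE)
    meth <- matrix(NA_real_, length(genes), length(all_samples),
                   dimnames = list(if (length(genes)) sprintf("meth_%s", genes)
                                   else character(0),
                                   all_samples))
    if (length(genes)) {
      base_mean <- 0.7
      for (type in names(truth$tumor)) {
        act <- truth$tumor[[type]]$activated
        cols <- colnames(act)
        for (gi in seq_along(genes)) {
          mu <- ifelse(act[genes[gi], ],
                       base_mean - spec$methylation_effect_size, base_mean)
          meth[gi, cols] <- round(rbeta_mean(length(cols), mu, 30), 4)
        }
      }
    }
    list(methylation = meth, maf = maf, clinical = clin)
  })
}

#' Run the full synthetic generator, optionally writing all files
#'
#' @param spec a `cohort_spec`.
#' @param outdir if non-NULL, write every artifact (expression TSVs, BED12
#'   gene models, BED6 element catalogs, bedGraph conservation tracks, GMT
#'   gene sets, MAF-lite, clinical TSV, methylation TSV, truth JSON) into
#'   this directory.
#' @return list with all in-memory objects plus `files` (named paths) when
#'   `outdir` is given.
#' @export
simulate_cohort <- function(spec, outdir = NULL) {
  np <- generate_normal_panel(spec)
  tc <- generate_tumor_cohorts(spec, np$truth)
  an <- generate_annotation(spec, tc$truth)
  truth <- an$truth
  truth$tumor <- tc$truth$tumor
  mm <- generate_methylation_mutations_clinical(spec, truth)
  out <- list(spec = spec, truth = truth, panel = np$panel,
              tissues = np$tissues, cohorts = tc$cohorts,
              genes = an$genes, elements = an$elements,
              phastcons = an$phastcons, phylop = an$phylop, gmt = an$gmt,
              methylation = mm$methylation, maf = mm$maf,
              clinical = mm$clinical)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(outdir, f)
    files <- c(
      panel = write_expression(np$panel, fp("normal_panel.tsv")),
      tissues = {
        data.table::fwrite(np$tissues, fp("tissue_labels.tsv"), sep = "\t")
        fp("tissue_labels.tsv")
      },
      genes = write_bed12(an$genes, fp("genes.bed")),
      phastcons = write_bedgraph(an$phastcons, fp("phastcons.bedGraph")),
      phylop = write_bedgraph(an$phylop, fp("phylop.bedGraph")),
      gmt = write_gmt(an$gmt, fp("genesets.gmt")),
      maf = write_maf_lite(mm$maf, fp("mutations.maf.tsv")),
      clinical = write_clinical(mm$clinical, fp("clinical.tsv")),
      truth = write_truth(truth, fp("truth.json"))
    )
    for (type in names(tc$cohorts)) {
      f <- fp(sprintf("tumor_%s.tsv", type))
      write_expression(tc$cohorts[[type]], f)
      files[sprintf("tumor_%s", type)] <- f
    }
    for (kind in names(an$elements)) {
      f <- fp(sprintf("elements_%s.bed", kind))
      write_bed6(an$elements[[kind]], f)
      files[sprintf("elements_%s", kind)] <- f
    }
    if (nrow(mm$methylation)) {
      dt <- data.table::data.table(probe_id = rownames(mm$methylation))
      dt <- cbind(dt, data.table::as.data.table(mm$methylation))
      data.table::fwrite(dt, fp("methylation.tsv"), sep = "\t")
      files["methylation"] <- fp("methylation.tsv")
    }
    out$files <- files
  }
  out
}
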