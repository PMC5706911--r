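# Shared fixture builders. Everything is generated in code at test time.

# scaled-down cohort for fast module tests; the acceptance suite uses the
# full default spec where a criterion prescribes it
small_spec <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(
    n_tissues = 6L, n_normal_individuals = 5L,
    n_tumor_samples_per_type = 60L, cancer_types = "LUAD",
    n_genes = 200L, n_lncrna = 80L,
    n_modules = 2L, module_size = 10L, module_lnc = 3L,
    n_terms = 10L, decoy_term_size = 15L,
    n_background_elements = 20L,
    seed = seed
  ), list(...))
  do.call(cohort_spec, args)
}

# minimal hand-built gene model table
make_genes <- function(df) {
  defaults <- data.frame(strand = "+", biotype = "lincRNA",
                         stringsAsFactors = FALSE)
  for (nm in names(defaults)) if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  if (!"chrom" %in% names(df)) df$chrom <- "chr1"
  gene_models(df)
}

expr_fixture <- function(values, unit = "RPKM",
                         genes = sprintf("g%d", seq_len(nrow(values))),
                         samples = sprintf("s%d", seq_len(ncol(values)))) {
  rownames(values) <- genes
  colnames(values) <- samples
  expression_matrix(values, unit)
}
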