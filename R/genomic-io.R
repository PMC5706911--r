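# File formats and core containers.
#
# All coordinates are handled internally as 0-based half-open intervals (the
# BED convention); conversion to the 1-based closed convention of
# GRanges/IRanges happens only at the boundary, in genes_to_granges() and the
# rtracklayer-backed readers/writers.

# ---- ExpressionMatrix -------------------------------------------------------

#' Construct an expression matrix
#'
#' A genes x samples matrix of non-negative expression values tagged with its
#' unit dialect. The unit decides default thresholds downstream: RPKM uses an
#' expression floor of 0.1, normalized read counts a floor of 5.
#'
#' @param values numeric matrix, rownames = gene ids, colnames = sample ids.
#' @param unit "RPKM" or "normalized_read_counts".
#' @return the matrix with class `expr_matrix` and a `unit` attribute.
#' @export
expression_matrix <- function(values, unit = c("RPKM", "normalized_read_counts")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  assert_that(is.numeric(values), "expression values must be numeric", "parse_error")
  assert_that((nrow(values) == 0 || !is.null(rownames(values))) &&
                (ncol(values) == 0 || !is.null(colnames(values))),
              "expression matrix needs gene ids (rownames) and sample ids (colnames)",
              "parse_error")
  assert_that(!anyDuplicated(rownames(values)), "duplicate gene ids", "parse_error")
  assert_that(!anyDuplicated(colnames(values)), "duplicate sample ids", "parse_error")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    ctl_stop("negative expression value at gene '%s'", "parse_error",
             rownames(values)[neg[1, 1]])
  }
  structure(values, unit = unit, class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "unit")))
  invisible(x)
}

#' Unit dialect of an expression matrix
#' @param x an `expr_matrix`.
#' @export
expr_unit <- function(x) attr(x, "unit") %||% "RPKM"

#' Default expression floor for a unit dialect
#'
#' RPKM matrices use the 0.1 floor, normalized read counts use 5.
#' @param unit unit string.
#' @export
default_floor <- function(unit) {
  switch(unit, RPKM = 0.1, normalized_read_counts = 5,
         ctl_stop("unknown expression unit '%s'", "config_error", unit))
}

#' Read / write an expression TSV
#'
#' TSV dialect: first column `gene_id`, remaining columns one per sample,
#' with a header line. Round-trips losslessly with [write_expression()].
#'
#' @param path file path.
#' @param unit unit dialect to tag the matrix with.
#' @return an `expr_matrix`.
#' @export
read_expression <- function(path, unit = c("RPKM", "normalized_read_counts")) {
  unit <- match.arg(unit)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
  assert_that(ncol(dt) >= 2, "expression TSV needs a gene_id column plus samples",
              "parse_error")
  gene_ids <- as.character(dt[[1]])
  body <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(body)) {
    bad <- which(!vapply(dt[, -1, with = FALSE], is.numeric, logical(1)))[1]
    ctl_stop("non-numeric expression column '%s'", "parse_error",
             names(dt)[bad + 1L])
  }
  neg <- which(rowSums(body < 0) > 0)
  if (length(neg) > 0) {
    ctl_stop("negative expression value at line %d (gene '%s')", "parse_error",
             neg[1] + 1L, gene_ids[neg[1]])
  }
  rownames(body) <- gene_ids
  expression_matrix(body, unit)
}

#' @rdname read_expression
#' @param x an `expr_matrix`.
#' @export
write_expression <- function(x, path) {
  dt <- data.table::data.table(gene_id = rownames(x))
  dt <- cbind(dt, data.table::as.data.table(unclass(x)))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# ---- Gene models ------------------------------------------------------------

LNCRNA_BIOTYPES <- c("3_prime_overlapping_ncRNA", "antisense", "lincRNA",
                     "sense_intronic", "sense_overlapping", "processed_transcript")
ALL_BIOTYPES <- c(LNCRNA_BIOTYPES, "protein_coding", "other")

#' Construct a gene-model table
#'
#' One row per gene: stranded genomic span, exon structure (list columns of
#' 0-based half-open intervals) and biotype. Invariants are checked:
#' 0 <= start < end, strand in {+,-}, exons sorted, non-overlapping and
#' contained in the gene span.
#'
#' @param df data.frame with columns gene_id, chrom, start, end, strand,
#'   biotype and list columns exons_start, exons_end (defaulted to the whole
#'   span when absent).
#' @return a `gene_models` data.table.
#' @export
gene_models <- function(df) {
  df <- data.table::as.data.table(df)
  need <- c("gene_id", "chrom", "start", "end", "strand", "biotype")
  assert_that(all(need %in% names(df)), "gene model table missing columns: %s",
              "parse_error", paste(setdiff(need, names(df)), collapse = ", "))
  assert_that(!anyDuplicated(df$gene_id), "duplicate gene ids", "parse_error")
  assert_that(all(df$strand %in% c("+", "-")),
              "gene strand must be '+' or '-'", "parse_error")
  assert_that(all(df$biotype %in% ALL_BIOTYPES),
              "unknown biotype", "parse_error")
  assert_that(all(df$start >= 0 & df$start < df$end),
              "gene coordinates must satisfy 0 <= start < end", "parse_error")
  if (!"exons_start" %in% names(df)) {
    df$exons_start <- as.list(df$start)
    df$exons_end <- as.list(df$end)
  }
  for (i in seq_len(nrow(df))) {
    es <- df$exons_start[[i]]; ee <- df$exons_end[[i]]
    ok <- length(es) == length(ee) && length(es) > 0 &&
      all(es < ee) && !is.unsorted(es, strictly = TRUE) &&
      all(es >= df$start[i]) && all(ee <= df$end[i]) &&
      (length(es) == 1 || all(es[-1] >= ee[-length(ee)]))
    if (!ok) {
      ctl_stop("gene '%s': exons must be sorted, non-overlapping and inside the span",
               "parse_error", df$gene_id[i])
    }
  }
  data.table::setattr(df, "class", c("gene_models", class(df)))
  df
}

#' Convert gene models (or any 0-based interval table) to GRanges
#'
#' @param df table with chrom, start, end and optionally strand columns,
#'   0-based half-open.
#' @return a [GenomicRanges::GRanges] (1-based closed).
#' @export
genes_to_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand); s[is.na(s) | s == "."] <- "*"; s
  } else "*"
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
  if ("gene_id" %in% names(df)) names(gr) <- df$gene_id
  if ("name" %in% names(df)) names(gr) <- df$name
  gr
}

#' Read / write gene models as BED12
#'
#' The BED name field carries `gene_id|biotype` so the biotype survives the
#' round trip; blocks encode the exon structure.
#'
#' @param path file path.
#' @export
read_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  assert_that(length(gr) > 0, "empty BED12 file", "parse_error")
  assert_that(all(GenomicRanges::width(gr) > 0),
              "BED interval with start >= end", "parse_error")
  assert_that(all(as.character(GenomicRanges::strand(gr)) %in% c("+", "-")),
              "gene models require an explicit +/- strand", "parse_error")
  nm <- gr$name
  parts <- data.table::tstrsplit(nm, "|", fixed = TRUE)
  biotype <- if (length(parts) >= 2) parts[[2]] else rep("other", length(gr))
  blocks <- gr$blocks
  if (is.null(blocks)) {
    blocks <- IRanges::IRangesList(lapply(GenomicRanges::width(gr), function(w)
      IRanges::IRanges(1L, w)))
  }
  start0 <- GenomicRanges::start(gr) - 1L
  exs <- mapply(function(b, s) s + IRanges::start(b) - 1L, blocks, start0,
                SIMPLIFY = FALSE)
  exe <- mapply(function(b, s) s + IRanges::end(b), blocks, start0,
                SIMPLIFY = FALSE)
  gene_models(data.table::data.table(
    gene_id = parts[[1]],
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype,
    exons_start = exs,
    exons_end = exe
  ))
}

#' @rdname read_bed12
#' @param genes a `gene_models` table.
#' @export
write_bed12 <- function(genes, path) {
  gr <- genes_to_granges(genes)
  gr$name <- paste(genes$gene_id, genes$biotype, sep = "|")
  gr$score <- 0L
  gr$thick <- IRanges::ranges(gr)
  gr$blocks <- IRanges::IRangesList(mapply(function(es, ee, s)
    IRanges::IRanges(start = es - s + 1L, end = ee - s),
    genes$exons_start, genes$exons_end, genes$start, SIMPLIFY = FALSE))
  names(gr) <- NULL
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read / write element intervals as BED6
#'
#' Elements may be strandless (`.`), returned as NA strand; gene models may
#' not. Coordinates come back 0-based half-open.
#'
#' @param path file path.
#' @return data.table with chrom, start, end, name, score, strand.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  assert_that(all(GenomicRanges::width(gr) > 0),
              "BED interval with start >= end", "parse_error")
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- NA_character_
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (is.null(gr$name)) sprintf("el%d", seq_along(gr)) else gr$name,
    score = if (is.null(gr$score)) 0 else as.numeric(gr$score),
    strand = s
  )
}

#' @rdname read_bed6
#' @param elements data.frame with chrom, start, end, name and optional
#'   score/strand columns.
#' @export
write_bed6 <- function(elements, path) {
  gr <- genes_to_granges(elements)
  gr$name <- elements$name
  gr$score <- if ("score" %in% names(elements)) elements$score else 0
  names(gr) <- NULL
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# ---- Score tracks -----------------------------------------------------------

#' Construct a per-base conservation score track
#'
#' Piecewise-constant scores over 0-based half-open intervals, non-overlapping
#' within each chromosome. PhastCons tracks must have values in \[0, 1\];
#' PhyloP values are unbounded reals.
#'
#' @param df table with chrom, start, end, value.
#' @param kind "phastcons" or "phylop".
#' @return a `score_track` (data.table with a `kind` attribute).
#' @export
score_track <- function(df, kind = c("phastcons", "phylop")) {
  kind <- match.arg(kind)
  dt <- data.table::as.data.table(df)[, c("chrom", "start", "end", "value")]
  assert_that(all(dt$start >= 0 & dt$start < dt$end),
              "track intervals must satisfy 0 <= start < end", "parse_error")
  if (kind == "phastcons") {
    assert_that(all(dt$value >= 0 & dt$value <= 1),
                "PhastCons values must lie in [0, 1]", "parse_error")
  }
  data.table::setorder(dt, chrom, start)
  ov <- dt[, any(start[-1] < end[-.N]), by = chrom][V1 == TRUE]
  assert_that(nrow(ov) == 0, "track intervals overlap on %s", "parse_error",
              paste(ov$chrom, collapse = ","))
  data.table::setattr(dt, "kind", kind)
  data.table::setattr(dt, "class", c("score_track", class(dt)))
  dt
}

#' Read / write a bedGraph score track
#' @param path file path.
#' @param kind track kind, see [score_track()].
#' @export
read_bedgraph <- function(path, kind = c("phastcons", "phylop")) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  score_track(data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    value = as.numeric(gr$score)
  ), kind = match.arg(kind))
}

#' @rdname read_bedgraph
#' @param track a `score_track`.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end),
                               score = track$value)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# ---- GMT / MAF-lite / clinical / truth --------------------------------------

#' Read / write gene-set collections in GMT format
#'
#' One set per line: name, description, then member genes (deduplicated).
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    assert_that(length(f) >= 3, "GMT line with fewer than 3 fields", "parse_error")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  assert_that(!anyDuplicated(names(sets)), "duplicate GMT set names", "parse_error")
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a MAF-lite mutation table
#'
#' Three tab-separated columns: sample_id, gene, variant_class.
#' @param path file path.
#' @export
read_maf_lite <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1:3))
  need <- c("sample_id", "gene", "variant_class")
  assert_that(all(need %in% names(dt)), "MAF-lite missing columns: %s",
              "parse_error", paste(setdiff(need, names(dt)), collapse = ", "))
  dt
}

#' @rdname read_maf_lite
#' @param maf data.frame with sample_id, gene, variant_class.
#' @export
write_maf_lite <- function(maf, path) {
  data.table::fwrite(data.table::as.data.table(maf), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read / write the clinical table
#'
#' Columns sample_id, age, gender, stage (I-IV), cancer_type; missing values
#' are encoded "NA" and handled complete-case by the model fitters.
#' @param path file path.
#' @export
read_clinical <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, na.strings = "NA")
  need <- c("sample_id", "age", "gender", "stage", "cancer_type")
  assert_that(all(need %in% names(dt)), "clinical table missing columns: %s",
              "parse_error", paste(setdiff(need, names(dt)), collapse = ", "))
  dt
}

#' @rdname read_clinical
#' @param clinical clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  data.table::fwrite(data.table::as.data.table(clinical), path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Read / write the planted-truth JSON
#' @param path file path.
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$module_assignment <- unlist(tr$module_assignment)
  tr
}

#' @rdname read_truth
#' @param truth a `synthetic_truth` list.
#' @export
write_truth <- function(truth, path) {
  public <- truth[c("ts_genes", "ct_genes", "eect_genes", "module_assignment",
                    "element_placements", "methylation_effect", "exclusive_pairs")]
  jsonlite::write_json(public, path, auto_unbox = FALSE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
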