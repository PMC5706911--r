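# Guilt-by-association functional annotation of lncRNAs.
#
# For each lncRNA, Spearman correlation against every tested protein-coding
# gene; the leading 10% positively and negatively correlated genes form the
# query set; each gene-set term is tested with an upper-tail hypergeometric
# over the tested-coding-gene universe and BH-adjusted; terms below alpha
# (default 0.01) annotate the lncRNA. Successfully annotated genes are then
# folded back into the database (expansion), and the CT-lncRNA set is tested
# for term enrichment against the expanded counts.

#' Construct an annotation database
#'
#' @param terms named list: term -> character vector of member genes.
#' @param universe the annotatable universe; defaults to the union of all
#'   members. Members outside an explicit universe are dropped (this is how
#'   the universe is restricted to tested genes).
#' @return an `annotation_db` list with `terms` and `universe`.
#' @export
annotation_db <- function(terms, universe = NULL) {
  assert_that(is.list(terms) && !is.null(names(terms)) && !anyDuplicated(names(terms)),
              "terms must be a uniquely named list", "config_error")
  terms <- lapply(terms, unique)
  if (is.null(universe)) {
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  } else {
    universe <- sort(unique(universe))
    terms <- lapply(terms, intersect, universe)
  }
  structure(list(terms = terms, universe = universe), class = "annotation_db")
}

#' Filter genes by expression support
#'
#' Keeps genes with expression strictly above `floor` in at least `min_frac`
#' of samples (the co-expression prefilter).
#'
#' @param expr `expr_matrix`.
#' @param floor expression floor (default: the matrix unit's floor).
#' @param min_frac minimum fraction of expressing samples.
#' @return character vector of retained gene ids.
#' @export
expression_filter <- function(expr, floor = NULL, min_frac = 0.01) {
  floor <- floor %||% default_floor(expr_unit(expr))
  frac <- rowMeans(unclass(expr) > floor)
  rownames(expr)[frac >= min_frac]
}

#' Spearman co-expression of lncRNAs against coding genes
#'
#' @param expr `expr_matrix` containing both gene groups.
#' @param lnc_ids,coding_ids row subsets to correlate.
#' @return matrix of Spearman rho, lncRNAs x coding genes. Constant rows
#'   yield NA correlations.
#' @export
coexpression_rho <- function(expr, lnc_ids, coding_ids) {
  x <- t(unclass(expr)[lnc_ids, , drop = FALSE])
  y <- t(unclass(expr)[coding_ids, , drop = FALSE])
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

#' Leading-decile co-expression partners of one lncRNA
#'
#' The top `frac` (floor) of coding genes by rho descending become positive
#' partners, the bottom `frac` ascending negative partners; ties at the
#' decile boundary are broken by gene id so selection is deterministic and
#' independent of input order.
#'
#' @param rho_row named numeric vector of rho against all tested coding
#'   genes (NAs dropped).
#' @param lncrna_id id recorded in the profile.
#' @param frac leading fraction per direction (default 0.10).
#' @return a `coexpression_profile` list with `lncrna_id`, `partners_pos`,
#'   `partners_neg` (data.tables with gene, rho).
#' @export
top_decile_partners <- function(rho_row, lncrna_id = NA_character_, frac = 0.10) {
  rho_row <- rho_row[!is.na(rho_row)]
  n <- length(rho_row)
  assert_that(n >= 10, "need at least 10 tested coding genes", "config_error")
  k <- floor(frac * n)
  ids <- names(rho_row)
  pos_ord <- order(-rho_row, ids)[seq_len(k)]
  neg_ord <- order(rho_row, ids)[seq_len(k)]
  structure(list(
    lncrna_id = lncrna_id,
    partners_pos = data.table::data.table(gene = ids[pos_ord],
                                          rho = unname(rho_row[pos_ord])),
    partners_neg = data.table::data.table(gene = ids[neg_ord],
                                          rho = unname(rho_row[neg_ord]))
  ), class = "coexpression_profile")
}

term_enrichment_table <- function(query, db) {
  N <- length(db$universe)
  query <- intersect(query, db$universe)
  n <- length(query)
  res <- data.table::data.table(
    term = names(db$terms),
    N = N,
    M = vapply(db$terms, length, integer(1)),
    n = n,
    m = vapply(db$terms, function(members)
      length(intersect(query, members)), integer(1))
  )
  res$p_raw <- hypergeom_enrich(res$N, res$M, res$n, res$m)
  res$p_bh <- bh_adjust(res$p_raw)
  res
}

#' Annotate one lncRNA by enrichment of its co-expression partners
#'
#' The query set is the union of positive and negative partners (or each
#' direction separately with `joint = FALSE`), intersected with the database
#' universe; terms with BH-adjusted hypergeometric p < alpha are assigned.
#' An empty partner set yields an empty annotation, not an error.
#'
#' @param profile a `coexpression_profile`.
#' @param db an `annotation_db` whose universe is the tested coding genes.
#' @param alpha BH-adjusted significance cutoff (default 0.01).
#' @param joint test positive and negative partners jointly (default) or
#'   separately (assigned terms are then the union).
#' @return list with `terms` (assigned term names) and `table` (per-term
#'   counts and p-values).
#' @export
annotate_lncrna <- function(profile, db, alpha = 0.01, joint = TRUE) {
  queries <- if (joint) {
    list(union(profile$partners_pos$gene, profile$partners_neg$gene))
  } else {
    list(profile$partners_pos$gene, profile$partners_neg$gene)
  }
  tabs <- lapply(queries, term_enrichment_table, db = db)
  tab <- data.table::rbindlist(tabs)
  assigned <- sort(unique(tab$term[tab$p_bh < alpha]))
  list(terms = assigned, table = tab)
}

#' Expand an annotation database with newly annotated genes
#'
#' Every successfully annotated gene is added to the member set of each of
#' its terms, and the universe is extended by the annotated genes; N and M
#' of subsequent enrichment tests then reflect the expansion. Idempotent
#' for a fixed annotation set.
#'
#' @param db an `annotation_db`.
#' @param annotations named list: gene -> character vector of assigned
#'   terms (genes with no terms may be present as empty vectors).
#' @param extra_coding_annotations optional second annotation set of the
#'   same shape (coding genes annotated by the same procedure), merged in.
#' @return the expanded `annotation_db`.
#' @export
expand_db <- function(db, annotations, extra_coding_annotations = NULL) {
  ann <- c(annotations, extra_coding_annotations %||% list())
  ann <- ann[lengths(ann) > 0]
  unknown <- setdiff(unique(unlist(ann, use.names = FALSE)), names(db$terms))
  assert_that(length(unknown) == 0, "annotation references unknown term(s): %s",
              "config_error", paste(unknown, collapse = ", "))
  terms <- db$terms
  for (g in names(ann)) {
    for (term in ann[[g]]) terms[[term]] <- union(terms[[term]], g)
  }
  structure(list(terms = terms,
                 universe = sort(union(db$universe, names(ann)))),
            class = "annotation_db")
}

#' Term enrichment of the CT-lncRNA set over the expanded database
#'
#' Per term, upper-tail hypergeometric with the expanded counts: N = genes
#' in the expanded universe, M = term members, n = annotated CT-lncRNAs
#' (CT genes present in the expanded universe), m = CT-lncRNAs in the term;
#' BH across terms, sorted by adjusted p.
#'
#' @param ct_lncrnas character vector of CT-lncRNA ids.
#' @param expanded_db the [expand_db()] result.
#' @return data.table (term, N, M, n, m, p_raw, p_bh) sorted by p_bh.
#' @export
ct_set_enrichment <- function(ct_lncrnas, expanded_db) {
  query <- intersect(ct_lncrnas, expanded_db$universe)
  assert_that(length(query) > 0, "no annotated CT-lncRNAs to test",
              "config_error")
  res <- term_enrichment_table(query, expanded_db)
  data.table::setorder(res, p_bh, p_raw, term)
  res
}

#' Run guilt-by-association annotation for a set of lncRNAs
#'
#' Convenience wrapper: filters genes, computes Spearman rho, selects
#' leading-decile partners, annotates each lncRNA and expands the database.
#'
#' @param expr `expr_matrix` holding lncRNAs and coding genes.
#' @param lnc_ids lncRNAs to annotate.
#' @param gmt named list of gene sets (coding members).
#' @param floor,min_frac expression filter, see [expression_filter()].
#' @param alpha per-lncRNA annotation cutoff.
#' @param frac leading fraction per direction.
#' @return list with `annotations` (named list lncRNA -> terms), `profiles`,
#'   `db` (tested-universe db) and `expanded_db`.
#' @export
annotate_lncrna_set <- function(expr, lnc_ids, gmt, floor = NULL,
                                min_frac = 0.01, alpha = 0.01, frac = 0.10) {
  tested <- expression_filter(expr, floor = floor, min_frac = min_frac)
  coding <- intersect(tested, unique(unlist(gmt, use.names = FALSE)))
  assert_that(length(coding) >= 10,
              "fewer than 10 tested coding genes in the database", "config_error")
  lnc_ids <- intersect(lnc_ids, rownames(expr))
  db <- annotation_db(gmt, universe = coding)
  rho <- coexpression_rho(expr, lnc_ids, coding)
  profiles <- lapply(lnc_ids, function(l) {
    row <- rho[l, ]
    if (all(is.na(row))) return(NULL)
    top_decile_partners(row, lncrna_id = l, frac = frac)
  })
  names(profiles) <- lnc_ids
  profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  annotations <- lapply(profiles, function(p) annotate_lncrna(p, db, alpha)$terms)
  list(annotations = annotations,
       profiles = profiles,
       db = db,
       expanded_db = expand_db(db, annotations))
}
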