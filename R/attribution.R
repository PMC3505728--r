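#' @importFrom stats phyper
NULL

#' Attribute modulated genes to preferential explanation categories
#'
#' Each gene receives exactly one category, the first that matches in the
#' fixed precedence order: conserved predicted target
#' (`TS_conserved`); non-conserved predicted target with PCT <
#' `pct_cutoff` (`TS_nonconserved_pct_lt`); non-conserved predicted
#' target with PCT >= `pct_cutoff` (`TS_nonconserved_pct_ge`); predicted
#' only by an alternate algorithm (`alt_algorithm_only`); carrying the
#' transcription-factor motif only (`tf_motif_only`); otherwise
#' `unexplained`.  Genes with PCT exactly at the cutoff fall in the
#' `>=` bin.
#'
#' @param genes character vector of modulated genes (non-empty).
#' @param ts_predictions prediction table with `gene`, `conserved`,
#'   `pct`.
#' @param alt_predictions character vector of genes predicted by an
#'   alternate algorithm (may be empty).
#' @param tf_regulon character vector of genes carrying the TF motif.
#' @param pct_cutoff PCT cutoff (default 0.1).
#' @return list with `records` (data.frame `gene`, `category`),
#'   `fractions` (named numeric over all categories, summing to 1) and
#'   `explained_fraction` (1 - unexplained fraction).
#' @export
attributeGenes <- function(genes, ts_predictions,
                           alt_predictions = character(),
                           tf_regulon = character(), pct_cutoff = 0.1) {
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("empty gene set")
  pr <- ts_predictions
  cons_genes <- pr$gene[!is.na(pr$conserved) & pr$conserved]
  noncons <- pr[!is.na(pr$conserved) & !pr$conserved, , drop = FALSE]
  lt_genes <- noncons$gene[!is.na(noncons$pct) & noncons$pct < pct_cutoff]
  ge_genes <- noncons$gene[!is.na(noncons$pct) & noncons$pct >= pct_cutoff]
  category <- ifelse(genes %in% cons_genes, "TS_conserved",
    ifelse(genes %in% lt_genes, "TS_nonconserved_pct_lt",
    ifelse(genes %in% ge_genes, "TS_nonconserved_pct_ge",
    ifelse(genes %in% alt_predictions, "alt_algorithm_only",
    ifelse(genes %in% tf_regulon, "tf_motif_only", "unexplained")))))
  fractions <- vapply(ATTRIBUTION_CATEGORIES,
                      function(k) mean(category == k), numeric(1))
  list(records = data.frame(gene = genes, category = category,
                            stringsAsFactors = FALSE),
       fractions = fractions,
       explained_fraction = 1 - fractions[["unexplained"]])
}

#' Gene-set over-representation by the hypergeometric test
#'
#' Upper-tail hypergeometric p-value per annotation term for the overlap
#' between a gene set and the term, against a stated universe.  Results
#' are sorted ascending by p with stable tie order by term id.  No
#' multiple-testing correction is applied; significance is a fixed
#' threshold per term source (default 1e-4, the motif-enrichment
#' convention; use 0.05 for pathway mode).
#'
#' @param gene_set character vector, must be a subset of `universe`.
#' @param universe character vector of all eligible genes.
#' @param annotation named list of character vectors (term -> genes).
#' @param alpha significance threshold on the raw p-value.
#' @return data.frame with `term`, `k` (overlap), `n` (set size in
#'   universe), `K` (term size in universe), `N` (universe size),
#'   `p_value`, `significant`.
#' @export
enrichGeneSets <- function(gene_set, universe, annotation, alpha = 1e-4) {
  gene_set <- unique(as.character(gene_set))
  universe <- unique(as.character(universe))
  outside <- setdiff(gene_set, universe)
  if (length(outside))
    stop("gene set members outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) " ...")
  if (!length(annotation) || is.null(names(annotation)))
    stop("'annotation' must be a named list of term gene sets")
  N <- length(universe)
  n <- length(gene_set)
  rows <- lapply(names(annotation), function(term) {
    tg <- intersect(unique(annotation[[term]]), universe)
    K <- length(tg)
    k <- length(intersect(gene_set, tg))
    # P(X >= k) for X ~ Hypergeom(N, K, n)
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  out$significant <- out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Consistency check for TF-driven secondary regulation
#'
#' Tests whether modulated genes devoid of a miRNA recognition element
#' are over-represented for a transcription-factor regulon — the
#' signature of secondary regulation through a TF that is itself a miRNA
#' target.  Reports the regulon's enrichment p within the MRE-devoid
#' modulated set, its rank among all supplied terms, and the fraction of
#' the set carrying the motif.
#'
#' @param modulated_no_mre character vector of modulated genes without a
#'   predicted MRE (non-empty).
#' @param universe character vector of retained (expressed) genes.
#' @param annotation named list of term gene sets; must contain
#'   `regulon_term`.
#' @param regulon_term name of the TF-regulon term.
#' @param alpha significance threshold (default 1e-4).
#' @return list with `enrichment` (full [enrichGeneSets()] table),
#'   `regulon_p`, `regulon_rank`, `fraction_with_motif`, `significant`.
#' @export
tfSecondaryConsistency <- function(modulated_no_mre, universe, annotation,
                                   regulon_term, alpha = 1e-4) {
  if (!length(modulated_no_mre)) stop("empty MRE-devoid modulated set")
  if (!regulon_term %in% names(annotation))
    stop("'", regulon_term, "' is not among the annotation terms")
  enr <- enrichGeneSets(modulated_no_mre, universe, annotation, alpha)
  i <- match(regulon_term, enr$term)
  list(enrichment = enr,
       regulon_p = enr$p_value[i],
       regulon_rank = i,
       fraction_with_motif = mean(modulated_no_mre %in%
                                    annotation[[regulon_term]]),
       significant = enr$significant[i])
}
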