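# Locus-overlap enrichment of TE families around gene clusters: 10-kb
# flank-and-merge region construction, per-family 2x2 contingency tables on
# the universe regions, one-sided Fisher's exact test, FDR correction.

#' Build query regions around a gene family of interest
#'
#' Every gene of the family is widened by `flank` bp on both sides, clipped
#' to its scaffold, and overlapping or touching windows are combined, so a
#' tandem cluster yields a single query region.
#'
#' @inheritParams flank_and_merge
#' @return merged region set labelled `"query"`.
#' @export
build_query_regions <- function(genes, scaffold_lengths, flank = 10000) {
  flank_and_merge(genes, scaffold_lengths, flank, label = "query")
}

#' Build the region universe around all annotated genes
#'
#' Same construction as [build_query_regions()] applied to the full gene
#' set: the merged regions are the counting units of the enrichment test.
#'
#' @inheritParams flank_and_merge
#' @return merged region set labelled `"universe"`.
#' @export
build_universe <- function(genes, scaffold_lengths, flank = 10000) {
  flank_and_merge(genes, scaffold_lengths, flank, label = "universe")
}

#' Contingency table for one TE family over the region universe
#'
#' Each universe region is classified on two axes: does it intersect a query
#' region (>= 1 bp; the query set is built from a subset of the same genes,
#' so query regions coincide with universe regions), and does it overlap at
#' least one TE copy of the family. Returns the 2x2 counts
#' `a` (query & TE), `b` (non-query & TE), `c` (query, no TE),
#' `d` (non-query, no TE).
#'
#' @param universe merged universe region set.
#' @param query merged query region set; every query region must intersect
#'   the universe.
#' @param te_intervals interval data.frame of the family's TE copies.
#' @param is_query optional precomputed query-membership vector along
#'   universe rows (used by [enrichment_scan()] to avoid recomputation).
#' @return named list `a`, `b`, `c`, `d` plus the logical vectors
#'   `is_query`, `has_te` along universe rows.
#' @export
make_contingency <- function(universe, query, te_intervals,
                             is_query = NULL) {
  if (nrow(universe) == 0L) stop("empty region universe")
  if (is.null(is_query)) {
    if (nrow(query) > 0L) {
      orphan <- !overlaps_any(query, universe)
      if (any(orphan))
        stop("query region overlapping no universe region (rows ",
             paste(which(orphan), collapse = ", "), ")")
    }
    is_query <- overlaps_any(universe, query)
  }
  has_te <- overlaps_any(universe, te_intervals)
  list(a = sum(is_query & has_te), b = sum(!is_query & has_te),
       c = sum(is_query & !has_te), d = sum(!is_query & !has_te),
       is_query = is_query, has_te = has_te)
}

#' One-sided Fisher's exact test for a 2x2 table
#'
#' Enrichment-direction (greater) test: the p-value is the hypergeometric
#' tail probability of tables with the observed margins whose query-overlap
#' count is at least the observed `a`. The odds ratio is the sample odds
#' ratio `ad/bc` (`Inf` when `bc = 0` and `ad > 0`).
#'
#' @param table list or vector with elements `a`, `b`, `c`, `d`.
#' @param alternative only `"greater"` (enrichment) is provided.
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(table, alternative = "greater") {
  stopifnot(alternative == "greater")
  a <- table[["a"]]; b <- table[["b"]]; c <- table[["c"]]; d <- table[["d"]]
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  m <- a + b          # regions overlapping the family
  n <- c + d          # regions not overlapping
  k <- a + c          # query regions
  p <- sum(stats::dhyper(seq(a, min(m, k)), m, n, k))
  p <- min(1, max(p, .Machine$double.xmin))
  or <- if (b * c == 0) { if (a * d == 0) NaN else Inf } else (a * d) / (b * c)
  list(p_value = p, odds_ratio = or)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; monotone, `q >= p` elementwise.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return vector of adjusted values (q-values in the BH sense).
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Storey q-values with a fixed lambda
#'
#' Estimates the null proportion as
#' `pi0 = min(1, mean(p > lambda) / (1 - lambda))` and applies the step-up
#' rule scaled by `pi0`. Used instead of BH when the number of tests is
#' large enough for `pi0` estimation to be stable.
#'
#' @param p p-values.
#' @param lambda tuning parameter (default 0.5).
#' @return q-values.
#' @export
storey_qvalue <- function(p, lambda = 0.5) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  pi0 <- min(1, mean(p > lambda, na.rm = TRUE) / (1 - lambda))
  pi0 <- max(pi0, 1 / length(p))  # guard against pi0 = 0
  q <- pi0 * stats::p.adjust(p, method = "BH")
  pmin(q, 1)
}

#' FDR correction choosing the estimator by test count
#'
#' BH when fewer than `storey_min` tests, Storey's estimator otherwise.
#'
#' @param p p-values.
#' @param storey_min minimum number of tests for Storey (default 100).
#' @return q-values.
#' @export
fdr_qvalue <- function(p, storey_min = 100) {
  if (length(p) >= storey_min) storey_qvalue(p) else bh_fdr(p)
}

#' Scan all TE families for enrichment near a gene family
#'
#' Builds the query and universe regions, forms one contingency table per TE
#' consensus family (and, when `order` labels are present, one per TE order
#' as an aggregate level), tests each with the one-sided Fisher's exact
#' test, and corrects for multiple testing within each level.
#'
#' @param family_genes intervals of the gene family of interest.
#' @param all_genes intervals of all annotated genes (the universe is built
#'   from these).
#' @param te_annotations interval data.frame with columns `family_id` and
#'   optionally `order` / `te_class`.
#' @param scaffold_lengths named vector of scaffold lengths.
#' @param flank flank size in bp (default 10000).
#' @return data.frame of class `enrichment_scan`, one row per family (level
#'   `"family"`) and per order (level `"order"`), sorted by q-value within
#'   level; columns `level`, `id`, `order`, `a`..`d`, `odds_ratio`,
#'   `p_value`, `q_value`.
#' @export
enrichment_scan <- function(family_genes, all_genes, te_annotations,
                            scaffold_lengths, flank = 10000) {
  universe <- build_universe(all_genes, scaffold_lengths, flank)
  query <- build_query_regions(family_genes, scaffold_lengths, flank)
  if (nrow(universe) == 0L) stop("empty region universe")
  if (is.null(te_annotations) || nrow(te_annotations) == 0L) {
    out <- data.frame(level = character(), id = character(),
                      order = character(), a = integer(), b = integer(),
                      c = integer(), d = integer(), odds_ratio = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("enrichment_scan", class(out))
    return(out)
  }
  if (nrow(query) > 0L && any(!overlaps_any(query, universe)))
    stop("query region overlapping no universe region")
  is_query <- overlaps_any(universe, query)
  test_level <- function(groups, level) {
    rows <- lapply(names(groups), function(id) {
      te <- groups[[id]]
      ct <- make_contingency(universe, query, te, is_query = is_query)
      ft <- fisher_exact(ct)
      data.frame(level = level, id = id,
                 order = if (!is.null(te$order)) te$order[1] else NA_character_,
                 a = ct$a, b = ct$b, c = ct$c, d = ct$d,
                 odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$q_value <- fdr_qvalue(out$p_value)
    out[order(out$q_value, out$p_value), , drop = FALSE]
  }
  fam <- split(te_annotations, te_annotations$family_id)
  res <- test_level(fam, "family")
  if (!is.null(te_annotations$order)) {
    ord <- split(te_annotations, te_annotations$order)
    res <- rbind(res, test_level(ord, "order"))
  }
  rownames(res) <- NULL
  attr(res, "n_universe") <- nrow(universe)
  attr(res, "n_query") <- nrow(query)
  class(res) <- c("enrichment_scan", class(res))
  res
}

#' @export
print.enrichment_scan <- function(x, ...) {
  cat(sprintf("TE enrichment scan: %d universe regions, %d query regions\n",
              attr(x, "n_universe"), attr(x, "n_query")))
  NextMethod()
}
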