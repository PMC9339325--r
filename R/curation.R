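# Curation rules for annotated chemoreceptor gene models: allele collapse at
# >= 90% protein identity, completeness / pseudogene calls, the C-terminal
# TYhhhhhQF domain check, and the repertoire summary tables.

# Default hydrophobic residue set for the 'h' positions of the GR domain
# motif: Kyte-Doolittle-positive residues plus the aromatics.
HYDROPHOBIC <- c("A", "V", "L", "I", "M", "F", "W", "C", "Y")

#' Percent identity between two proteins under global alignment
#'
#' Sequences are globally aligned (Needleman-Wunsch, BLOSUM62, gap open 10 /
#' extend 0.5) and identity is the number of identical aligned positions
#' divided by the number of columns where neither sequence has a gap. The
#' measure is symmetric.
#'
#' @param a,b protein sequences (character scalars, nonempty).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be nonempty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- s1 != "-" & s2 != "-"
  if (!any(both)) return(0)
  sum(s1[both] == s2[both]) / sum(both)
}

#' Collapse allelic sequences at an identity threshold
#'
#' Records whose proteins share at least `threshold` identity are clustered
#' by single linkage (each sequence is compared against all others, as in
#' manual inspection of a full alignment). Within each cluster only the
#' longest protein keeps its prior category; every other member becomes
#' `category = "allele"` with `allele_of` pointing at the retained record.
#' Length ties break to the lexicographically smallest `gene_id` so the
#' operation is deterministic and order-invariant.
#'
#' @param records data.frame with at least `gene_id`, `protein` and
#'   (optionally) `category` columns.
#' @param threshold identity threshold (default 0.90).
#' @return `records` with `category` / `allele_of` updated.
#' @export
collapse_alleles <- function(records, threshold = 0.90) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (is.null(records$allele_of)) records$allele_of <- NA_character_
  if (is.null(records$category)) records$category <- "partial"
  if (n <= 1L) return(records)
  # union-find over pairs at >= threshold identity (single linkage)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (pairwise_identity(records$protein[i], records$protein[j]) >=
          threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  for (cl in split(seq_len(n), comp)) {
    if (length(cl) == 1L) next
    len <- nchar(records$protein[cl])
    keep <- cl[order(-len, records$gene_id[cl])][1L]
    drop <- setdiff(cl, keep)
    records$category[drop] <- "allele"
    records$allele_of[drop] <- records$gene_id[keep]
  }
  records
}

#' Classify a gene model as complete, partial or pseudogene
#'
#' A model with one or more internal (premature) stop codons is a pseudogene.
#' Otherwise it is complete when a start codon and a terminal stop codon are
#' both present and the protein is strictly longer than 350 amino acids;
#' anything else is partial. The protein is taken as the translation of the
#' CDS up to the first stop.
#'
#' @param cds nucleotide CDS (may be `NA` if `protein` given directly).
#' @param protein protein sequence; derived from `cds` when missing. A
#'   trailing `*` denotes a terminal stop, internal `*` a premature stop.
#' @param min_complete_aa completeness length threshold (strict `>`,
#'   default 350).
#' @return one of `"complete"`, `"partial"`, `"pseudogene"`.
#' @export
classify_gene <- function(cds = NA, protein = NULL, min_complete_aa = 350) {
  if (is.null(protein)) {
    if (is.na(cds)) stop("either cds or protein is required")
    protein <- translate_cds(cds)
  }
  has_terminal_stop <- endsWith(protein, "*")
  body <- sub("\\*$", "", protein)
  if (grepl("\\*", body)) return("pseudogene")
  has_start <- startsWith(body, "M")
  if (has_start && has_terminal_stop && nchar(body) > min_complete_aa)
    "complete"
  else
    "partial"
}

#' Translate a CDS with the standard genetic code
#'
#' Codons containing `N` translate to `X`; translation runs through the whole
#' sequence (stops appear as `*`), truncating a trailing partial codon.
#'
#' @param cds nucleotide sequence over `A,C,G,T,N`.
#' @return protein string.
#' @export
translate_cds <- function(cds) {
  if (!nzchar(cds)) stop("empty CDS")
  nc <- 3L * (nchar(cds) %/% 3L)
  cds <- substr(cds, 1L, nc)
  as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "solve",
    no.init.codon = TRUE))
}

#' Check for the conserved C-terminal GR domain motif
#'
#' Searches for the degenerate pattern `TYhhhhhQF` (T, Y, five hydrophobic
#' residues, Q, F) -- the conserved motif of transmembrane domain 7 of
#' insect gustatory receptors -- within a C-terminal window. A miss flags
#' the model for inspection; it is not a rejection criterion.
#'
#' @param protein protein sequence (terminal `*` ignored).
#' @param window number of C-terminal residues searched (default 100).
#' @param hydrophobic residue set accepted at the `h` positions.
#' @return list with `found` (logical) and `position` (1-based start within
#'   the full protein, `NA` if absent).
#' @export
motif_check <- function(protein, window = 100,
                        hydrophobic = HYDROPHOBIC) {
  protein <- sub("\\*$", "", protein)
  n <- nchar(protein)
  from <- max(1L, n - as.integer(window) + 1L)
  tail_seq <- substr(protein, from, n)
  h <- paste0("[", paste(hydrophobic, collapse = ""), "]")
  pat <- paste0("TY", strrep(h, 5), "QF")
  m <- regexpr(pat, tail_seq)
  if (m[1] == -1L) list(found = FALSE, position = NA_integer_)
  else list(found = TRUE, position = from + as.integer(m[1]) - 1L)
}

#' Summarize a curated repertoire (category counts table)
#'
#' Produces the per-species summary: counts of complete, partial, pseudogene
#' and allele records, the annotated total, the final repertoire size (total
#' minus pseudogenes and alleles), and each category's percentage of the
#' total rounded to the nearest integer.
#'
#' @param records curated records data.frame with a `category` column, or a
#'   named vector/list of category counts.
#' @return object of class `repertoire_summary`.
#' @export
summarize_repertoire <- function(records) {
  cats <- c("complete", "partial", "pseudogene", "allele")
  if (is.data.frame(records)) {
    counts <- vapply(cats, function(k) sum(records$category == k), numeric(1))
  } else {
    counts <- stats::setNames(rep(0, 4), cats)
    given <- unlist(records)
    bad <- setdiff(names(given), cats)
    if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
    counts[names(given)] <- given
  }
  total <- sum(counts)
  final <- total - counts[["pseudogene"]] - counts[["allele"]]
  pct <- if (total > 0) round(100 * counts / total) else counts * 0
  structure(list(counts = counts, total = total, final_count = final,
                 percent = pct),
            class = "repertoire_summary")
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat("Repertoire summary\n")
  for (k in names(x$counts))
    cat(sprintf("  %-10s %4d (%d%%)\n", k, x$counts[[k]], x$percent[[k]]))
  cat(sprintf("  total      %4d\n", x$total))
  cat(sprintf("  final (no pseudogenes/alleles) %d\n", x$final_count))
  invisible(x)
}

#' Per-clade counts and proportion of the functional repertoire
#'
#' Counts complete + partial records per expansion clade and reports the
#' clade total as a percentage (1 decimal) of the functional repertoire
#' (complete + partial genes). Clade labels on pseudogenes or alleles are an
#' error: those records are excluded upstream.
#'
#' @param records curated records with `category` and `clade` columns
#'   (`clade` may be `NA` for genes outside the named expansion clades), or
#'   `NULL` when `clade_counts` is given directly.
#' @param clade_counts optional named vector of per-clade counts (bypasses
#'   `records`); requires `functional_total`.
#' @param functional_total complete + partial gene count used as the
#'   percentage denominator; derived from `records` when omitted.
#' @return data.frame with one row per clade plus a `Total` row carrying the
#'   percentage.
#' @export
clade_proportion <- function(records = NULL, clade_counts = NULL,
                             functional_total = NULL) {
  if (is.null(clade_counts)) {
    stopifnot(is.data.frame(records))
    labelled <- !is.na(records$clade) & nzchar(as.character(records$clade))
    bad <- labelled & records$category %in% c("pseudogene", "allele")
    if (any(bad))
      stop("clade label on pseudogene/allele record: ",
           paste(records$gene_id[bad], collapse = ", "))
    keep <- records$category %in% c("complete", "partial")
    if (is.null(functional_total)) functional_total <- sum(keep)
    tab <- table(records$clade[keep & labelled])
    clade_counts <- stats::setNames(as.numeric(tab), names(tab))
  } else if (is.null(functional_total)) {
    stop("functional_total is required when clade_counts are given directly")
  }
  clade_total <- sum(clade_counts)
  pct <- round(100 * clade_total / functional_total, 1)
  out <- data.frame(clade = c(names(clade_counts), "Total"),
                    count = c(unname(clade_counts), clade_total),
                    stringsAsFactors = FALSE)
  out$percent <- c(rep(NA_real_, length(clade_counts)), pct)
  out
}

#' Genome size from flow cytometry
#'
#' 1C genome size estimated as the ratio of the sample's 2C fluorescence
#' peak to the co-prepared standard's 2C peak, times the standard's known 1C
#' size (Drosophila virilis, 328 Mbp, by default).
#'
#' @param sample_2C_fluor mean 2C fluorescence of the sample peak.
#' @param standard_2C_fluor mean 2C fluorescence of the standard peak.
#' @param standard_1C_Mbp 1C size of the standard in Mbp.
#' @return estimated 1C genome size in Mbp.
#' @export
genome_size_from_cytometry <- function(sample_2C_fluor, standard_2C_fluor,
                                       standard_1C_Mbp = 328) {
  if (sample_2C_fluor <= 0 || standard_2C_fluor <= 0 ||
      standard_1C_Mbp <= 0)
    stop("fluorescence values and standard size must be positive")
  sample_2C_fluor / standard_2C_fluor * standard_1C_Mbp
}
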