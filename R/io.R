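#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file (nucleotide or protein).
#' @return named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stats::setNames(as.character(set), ids)
}

#' Write a named character vector as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read GFF3 features as internal intervals
#'
#' GFF3 is 1-based closed; coordinates are converted to the internal 0-based
#' half-open convention (`start - 1`, `end` unchanged).
#'
#' @param path GFF3 file.
#' @param feature_filter optional character vector of `type` values to keep
#'   (e.g. `"gene"`).
#' @return interval data.frame with extra columns `type`, `ID` (from the
#'   attributes column where present) and `source`.
#' @export
read_gff3 <- function(path, feature_filter = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(feature_filter))
    gr <- gr[as.character(gr$type) %in% feature_filter]
  n <- length(gr)
  if (n == 0L) {
    out <- gintervals(character(), integer(), integer())
    out$type <- character(0); out$ID <- character(0)
    return(out)
  }
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, n)
  out <- gintervals(as.character(GenomeInfoDb::seqnames(gr)),
                    BiocGenerics::start(gr) - 1L,
                    BiocGenerics::end(gr),
                    strand)
  out$type <- as.character(gr$type)
  out$ID <- ids
  out
}

#' Write intervals to GFF3
#'
#' Internal 0-based half-open coordinates are converted back to GFF3's
#' 1-based closed convention, so `read_gff3(write_gff3(x))` is the identity
#' on coordinates.
#'
#' @param intervals interval data.frame; optional columns `type`, `ID`.
#' @param path output path.
#' @param source value for the GFF3 source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(intervals, path, source = "chemrep") {
  type <- if (!is.null(intervals$type)) intervals$type else "region"
  id <- if (!is.null(intervals$ID)) intervals$ID
        else sprintf("region%04d", seq_len(nrow(intervals)))
  lines <- c("##gff-version 3",
             sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                     intervals$scaffold, source, type,
                     as.integer(intervals$start) + 1L,
                     as.integer(intervals$end),
                     intervals$strand, id))
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file as internal intervals
#'
#' BED is already 0-based half-open, so coordinates pass through unchanged.
#'
#' @param path BED file (3-6 columns).
#' @return interval data.frame with a `name` column when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  strand <- if (ncol(raw) >= 6) raw[[6]] else "."
  out <- gintervals(raw[[1]], raw[[2]], raw[[3]], strand)
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  out
}

#' Read a rooted tree from a newick file or string
#'
#' @param x path to a newick file, or a newick string.
#' @return an `ape::phylo` object; errors if the tree is unrooted.
#' @export
read_tree <- function(x) {
  tr <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tr)) stop("could not parse newick input")
  if (!ape::is.rooted(tr)) stop("tree must be rooted")
  tr
}

#' Map gene-tree leaves to species via a prefix map
#'
#' Gene identifiers carry a species prefix (e.g. `"Slit_GR12"`); the prefix
#' map translates prefixes to species-tree leaf names. Unmapped leaves are an
#' error.
#'
#' @param labels character vector of gene leaf labels.
#' @param prefix_map named character vector, `prefix -> species name`.
#'   Prefixes are matched at the start of the label; the longest matching
#'   prefix wins.
#' @return character vector of species names along `labels`.
#' @export
species_of_leaf <- function(labels, prefix_map) {
  if (is.null(names(prefix_map))) stop("prefix_map must be named")
  pfx <- names(prefix_map)[order(nchar(names(prefix_map)), decreasing = TRUE)]
  vapply(labels, function(lab) {
    for (p in pfx) if (startsWith(lab, p)) return(unname(prefix_map[[p]]))
    stop("gene leaf '", lab, "' matches no prefix in the prefix map")
  }, character(1), USE.NAMES = FALSE)
}
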