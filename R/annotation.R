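# Iterative homology-based annotation: six-frame translated search (an
# exact-DP stand-in for tblastn), collinear chaining of HSPs into exon/gene
# models, and the iterate-until-no-new-gene loop used to exhaust a gene
# family in a genome.

#' Search and annotation parameters
#'
#' @param substitution_matrix scoring matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend gap penalties (positive costs; defaults 11/1,
#'   the classic protein-search setting).
#' @param min_score minimum local-alignment raw score to report an HSP --
#'   plays the role of an e-value cutoff in the exact-DP search.
#' @param min_identity minimum HSP identity fraction.
#' @param max_intron maximum genomic gap bridged inside a gene model, bp
#'   (default 50000, the standard noctuid RNA-mapping bound).
#' @param allele_threshold protein identity at or above which two models are
#'   alleles (default 0.90).
#' @param min_complete_aa completeness length threshold (strict `>`).
#' @param max_hsps_per_frame cap on HSPs reported per query/scaffold/frame.
#' @param min_reciprocal_overlap reciprocal-overlap fraction (of the shorter
#'   model) above which two models on one locus are reduced to the
#'   higher-scoring one.
#' @return list of class `search_params`.
#' @export
search_params <- function(substitution_matrix = "BLOSUM62", gap_open = 11,
                          gap_extend = 1, min_score = 60, min_identity = 0,
                          max_intron = 50000, allele_threshold = 0.90,
                          min_complete_aa = 350, max_hsps_per_frame = 25,
                          min_reciprocal_overlap = 0.5) {
  stopifnot(min_score > 0, min_identity >= 0, min_identity <= 1,
            max_intron >= 0, allele_threshold >= 0, allele_threshold <= 1)
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 min_score = min_score, min_identity = min_identity,
                 max_intron = max_intron,
                 allele_threshold = allele_threshold,
                 min_complete_aa = min_complete_aa,
                 max_hsps_per_frame = max_hsps_per_frame,
                 min_reciprocal_overlap = min_reciprocal_overlap),
            class = "search_params")
}

#' Six-frame translation
#'
#' Translates a nucleotide sequence in all six reading frames (three on the
#' forward strand, three on the reverse complement) with the standard
#' genetic code; codons containing `N` translate to `X`, stops to `*`.
#'
#' @param seq nucleotide sequence over `A,C,G,T,N`.
#' @return named character vector with names `+1,+2,+3,-1,-2,-3`.
#' @export
six_frame_translate <- function(seq) {
  if (!nzchar(seq)) stop("empty sequence")
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    n <- length(s) - off
    n <- n - n %% 3L
    if (n < 3L) return("")
    as.character(Biostrings::translate(
      Biostrings::subseq(s, off + 1L, off + n),
      if.fuzzy.codon = "solve", no.init.codon = TRUE))
  }
  out <- c(one(fwd, 0L), one(fwd, 1L), one(fwd, 2L),
           one(rev, 0L), one(rev, 1L), one(rev, 2L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# map aa coordinates in frame `frame` of a scaffold of length L to genomic
# 0-based half-open coordinates
frame_to_genomic <- function(frame, p_start, p_end, L) {
  f <- abs(frame)
  r0 <- (f - 1L) + 3L * (p_start - 1L)
  r1 <- (f - 1L) + 3L * p_end
  if (frame > 0) c(start = r0, end = r1)
  else c(start = L - r1, end = L - r0)
}

#' Exact translated search of protein queries against a genome
#'
#' Emulates a translated homology search (tblastn) by exhaustive local
#' alignment (Smith-Waterman via `pairwiseAlignment`) of every query
#' against all six reading frames of every scaffold. Multiple HSPs per
#' frame are recovered by masking each reported alignment and re-searching
#' until the score falls below `min_score`. Deterministic: no heuristic
#' seeding.
#'
#' @param query_proteins named character vector of protein queries.
#' @param genome named character vector of scaffold sequences.
#' @param params [search_params()].
#' @return data.frame of HSPs: `query_id`, `scaffold`, `frame`, `strand`,
#'   `q_start`/`q_end` (1-based aa, closed), `g_start`/`g_end` (0-based
#'   half-open bp), `score`, `identity`. Zero rows when nothing scores
#'   above threshold.
#' @export
translated_search <- function(query_proteins, genome,
                              params = search_params()) {
  stopifnot(length(query_proteins) > 0, length(genome) > 0)
  if (is.null(names(query_proteins)) || is.null(names(genome)))
    stop("queries and genome must be named")
  hits <- list()
  for (sc in names(genome)) {
    L <- nchar(genome[[sc]])
    frames <- six_frame_translate(genome[[sc]])
    for (fr_name in names(frames)) {
      subject0 <- frames[[fr_name]]
      if (!nzchar(subject0)) next
      frame <- as.integer(fr_name)
      for (qid in names(query_proteins)) {
        subject <- subject0
        for (iter in seq_len(params$max_hsps_per_frame)) {
          pa <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(query_proteins[[qid]]),
            Biostrings::AAString(subject),
            type = "local",
            substitutionMatrix = params$substitution_matrix,
            gapOpening = params$gap_open,
            gapExtension = params$gap_extend)
          sc_score <- Biostrings::score(pa)
          if (sc_score < params$min_score) break
          s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)),
                         "")[[1]]
          s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)),
                         "")[[1]]
          both <- s1 != "-" & s2 != "-"
          ident <- if (any(both)) sum(s1[both] == s2[both]) / sum(both) else 0
          ss <- Biostrings::start(Biostrings::subject(pa))
          se <- Biostrings::end(Biostrings::subject(pa))
          g <- frame_to_genomic(frame, ss, se, L)
          if (ident >= params$min_identity) {
            hits[[length(hits) + 1L]] <- data.frame(
              query_id = qid, scaffold = sc, frame = frame,
              strand = if (frame > 0) "+" else "-",
              q_start = Biostrings::start(Biostrings::pattern(pa)),
              q_end = Biostrings::end(Biostrings::pattern(pa)),
              g_start = unname(g["start"]), g_end = unname(g["end"]),
              score = sc_score, identity = ident,
              stringsAsFactors = FALSE)
          }
          # mask the reported segment and look for further HSPs
          substr(subject, ss, se) <- strrep("X", se - ss + 1L)
        }
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(query_id = character(), scaffold = character(),
                      frame = integer(), strand = character(),
                      q_start = integer(), q_end = integer(),
                      g_start = integer(), g_end = integer(),
                      score = numeric(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$scaffold, out$g_start, -out$score), , drop = FALSE]
}

#' Chain collinear HSPs into gene models
#'
#' HSPs of one query on one scaffold and strand are chained when collinear
#' in both the query and the genome with genomic gaps at most `max_intron`;
#' chaining maximizes the summed HSP score (exact dynamic program). Chains
#' are extracted best-first; each chain becomes a draft gene model whose
#' exons are the chained HSP genomic ranges.
#'
#' @param hsps HSP data.frame from [translated_search()] (any mix of
#'   queries/scaffolds/strands; chaining is done within each group).
#' @param params [search_params()].
#' @return list of gene-model lists: `query_id`, `scaffold`, `strand`,
#'   `exons` (interval data.frame), `score`, `q_start`, `q_end`.
#' @export
chain_hsps <- function(hsps, params = search_params()) {
  if (nrow(hsps) == 0L) return(list())
  groups <- split(hsps, interaction(hsps$query_id, hsps$scaffold,
                                    hsps$strand, drop = TRUE))
  models <- list()
  for (g in groups) {
    g <- g[order(g$q_start, g$q_end), , drop = FALSE]
    remaining <- g
    while (nrow(remaining) > 0L) {
      n <- nrow(remaining)
      dp <- remaining$score
      prev <- rep(NA_integer_, n)
      if (n > 1L) {
        for (i in seq(2L, n)) {
          for (j in seq_len(i - 1L)) {
            if (remaining$q_start[i] <= remaining$q_end[j]) next
            if (remaining$strand[i] == "+") {
              gap <- remaining$g_start[i] - remaining$g_end[j]
            } else {
              gap <- remaining$g_start[j] - remaining$g_end[i]
            }
            if (gap < 0 || gap > params$max_intron) next
            cand <- dp[j] + remaining$score[i]
            if (cand > dp[i]) { dp[i] <- cand; prev[i] <- j }
          }
        }
      }
      best <- which.max(dp)
      chain <- best
      while (!is.na(prev[chain[1]])) chain <- c(prev[chain[1]], chain)
      ch <- remaining[chain, , drop = FALSE]
      exons <- gintervals(ch$scaffold, ch$g_start, ch$g_end, ch$strand)
      exons <- exons[order(exons$start), , drop = FALSE]
      models[[length(models) + 1L]] <- list(
        query_id = ch$query_id[1], scaffold = ch$scaffold[1],
        strand = ch$strand[1], exons = exons, score = dp[best],
        q_start = min(ch$q_start), q_end = max(ch$q_end))
      remaining <- remaining[-chain, , drop = FALSE]
    }
  }
  models
}

# extract the spliced CDS of a gene model from the genome and translate it
model_sequences <- function(model, genome) {
  seqs <- substring(genome[[model$scaffold]],
                    model$exons$start + 1L, model$exons$end)
  if (model$strand == "+") {
    cds <- paste(seqs, collapse = "")
  } else {
    rc <- vapply(rev(seqs), function(s)
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
      character(1))
    cds <- paste(rc, collapse = "")
  }
  list(cds = cds, protein = translate_cds(cds))
}

model_span <- function(model) {
  c(start = min(model$exons$start), end = max(model$exons$end))
}

# reciprocal overlap of two models' genomic spans, relative to the shorter
reciprocal_overlap <- function(m1, m2) {
  if (m1$scaffold != m2$scaffold) return(0)
  s1 <- model_span(m1); s2 <- model_span(m2)
  ov <- min(s1["end"], s2["end"]) - max(s1["start"], s2["start"])
  if (ov <= 0) return(0)
  ov / min(s1["end"] - s1["start"], s2["end"] - s2["start"])
}

#' Iterative annotation of a gene family
#'
#' Runs the translated search with the seed queries, chains HSPs into gene
#' models, keeps one model per locus (reciprocal overlap above the
#' threshold resolves to the higher-scoring model), then adds the proteins
#' of newly accepted models to the query set and repeats until a full round
#' discovers no new locus. Newly proposed loci overlapping an accepted
#' locus are discarded, so the accepted repertoire only grows and the loop
#' terminates.
#'
#' @param seed_queries named character vector of seed proteins.
#' @param genome named character vector of scaffolds.
#' @param params [search_params()].
#' @param max_rounds safety bound on iterations.
#' @return data.frame of accepted gene models (`gene_id`, `scaffold`,
#'   `start`, `end`, `strand`, `n_exons`, `score`, `round`, `cds`,
#'   `protein`) with the per-model exon tables in attribute `"exons"` and
#'   the per-round accepted-gene counts in attribute `"rounds"`.
#' @export
iterate_annotation <- function(seed_queries, genome,
                               params = search_params(),
                               max_rounds = 25L) {
  stopifnot(length(seed_queries) > 0)
  accepted <- list()
  queries <- seed_queries
  round_log <- integer(0)
  for (round in seq_len(max_rounds)) {
    hsps <- translated_search(queries, genome, params)
    cands <- chain_hsps(hsps, params)
    # order candidates by score, resolve loci best-first
    if (length(cands)) {
      cands <- cands[order(-vapply(cands, `[[`, numeric(1), "score"))]
    }
    new_models <- list()
    for (cand in cands) {
      clash_new <- any(vapply(new_models, function(m)
        reciprocal_overlap(cand, m) > params$min_reciprocal_overlap,
        logical(1)))
      span <- model_span(cand)
      clash_old <- any(vapply(accepted, function(m) {
        if (m$scaffold != cand$scaffold) return(FALSE)
        s <- model_span(m)
        span["start"] < s["end"] && s["start"] < span["end"]
      }, logical(1)))
      if (!clash_new && !clash_old)
        new_models[[length(new_models) + 1L]] <- cand
    }
    round_log <- c(round_log, length(new_models))
    if (!length(new_models)) break
    new_queries <- character(0)
    for (m in new_models) {
      sq <- model_sequences(m, genome)
      m$cds <- sq$cds
      m$protein <- sq$protein
      m$round <- round
      accepted[[length(accepted) + 1L]] <- m
      prot <- sub("\\*$", "", gsub("\\*", "X", sq$protein))
      if (nzchar(prot))
        new_queries[paste0("locus", length(accepted))] <- prot
    }
    queries <- c(queries, new_queries)
  }
  # deterministic ids ordered by genomic position
  if (!length(accepted)) {
    out <- data.frame(gene_id = character(), scaffold = character(),
                      start = integer(), end = integer(),
                      strand = character(), n_exons = integer(),
                      score = numeric(), round = integer(),
                      cds = character(), protein = character(),
                      stringsAsFactors = FALSE)
    attr(out, "rounds") <- round_log
    attr(out, "exons") <- list()
    return(out)
  }
  ord <- order(vapply(accepted, `[[`, character(1), "scaffold"),
               vapply(accepted, function(m) model_span(m)["start"],
                      numeric(1)))
  accepted <- accepted[ord]
  out <- data.frame(
    gene_id = sprintf("gene%03d", seq_along(accepted)),
    scaffold = vapply(accepted, `[[`, character(1), "scaffold"),
    start = vapply(accepted, function(m) unname(model_span(m)["start"]),
                   numeric(1)),
    end = vapply(accepted, function(m) unname(model_span(m)["end"]),
                 numeric(1)),
    strand = vapply(accepted, `[[`, character(1), "strand"),
    n_exons = vapply(accepted, function(m) nrow(m$exons), integer(1)),
    score = vapply(accepted, `[[`, numeric(1), "score"),
    round = vapply(accepted, `[[`, integer(1), "round"),
    cds = vapply(accepted, `[[`, character(1), "cds"),
    protein = vapply(accepted, `[[`, character(1), "protein"),
    stringsAsFactors = FALSE)
  attr(out, "rounds") <- round_log
  attr(out, "exons") <- lapply(accepted, `[[`, "exons")
  out
}
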