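# Six-frame translated search, HSP chaining, and the iterative annotation
# loop, on small constructed genomes with planted genes.

blosum62_annot <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
})

# embed CDS fragments into a random genomic background
make_scaffold <- function(pieces, at, total, seed) {
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), total, TRUE), collapse = "")
  for (i in seq_along(pieces))
    substr(s, at[i] + 1L, at[i] + nchar(pieces[i])) <- pieces[i]
  s
}

test_that("six_frame_translate follows the code table in all frames", {
  fr <- six_frame_translate("ATGAAATAG")
  expect_equal(fr[["+1"]], "MK*")
  expect_equal(fr[["+2"]], "*N")   # TGA AAT AG
  # reverse strand of CAT is ATG -> M
  expect_equal(six_frame_translate("CAT")[["-1"]], "M")
  expect_error(six_frame_translate(""), "empty")
  # random 300-mer: frame +1 equals codon-by-codon lookup
  set.seed(55)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  codons <- substring(s, seq(1, 298, 3), seq(3, 300, 3))
  lookup <- paste(Biostrings::GENETIC_CODE[codons], collapse = "")
  expect_equal(six_frame_translate(s)[["+1"]], lookup)
})

test_that("translated_search finds a planted identical segment", {
  set.seed(17)
  prot <- chemrep:::random_protein(80)
  cds <- chemrep:::random_cds_for(prot)
  genome <- c(scf1 = make_scaffold(cds, 501, 2000, seed = 18))
  hits <- translated_search(c(q = prot), genome)
  expect_gte(nrow(hits), 1L)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$identity, 1.0)
  expect_equal(top$g_start, 501)
  expect_equal(top$g_end, 501 + nchar(cds))
  expect_equal(top$strand, "+")
  # the reported genomic range really translates to the aligned query
  sub <- substr(genome[["scf1"]], top$g_start + 1, top$g_end)
  expect_equal(translate_cds(sub),
               substr(prot, top$q_start, top$q_end))
})

test_that("translated_search locates reverse-strand genes", {
  set.seed(27)
  prot <- chemrep:::random_protein(60)
  cds <- chemrep:::random_cds_for(prot)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  genome <- c(scf1 = make_scaffold(rc, 301, 1500, seed = 28))
  hits <- translated_search(c(q = prot), genome)
  top <- hits[which.max(hits$score), ]
  expect_equal(top$strand, "-")
  expect_equal(top$g_start, 301)
  expect_equal(top$g_end, 301 + nchar(cds))
})

test_that("no query residue scoring above threshold yields zero HSPs", {
  genome <- c(scf1 = strrep("ACGT", 300))
  hits <- translated_search(c(q = strrep("W", 40)), genome,
                            search_params(min_score = 80))
  expect_equal(nrow(hits), 0L)
})

test_that("local alignment scores match a Smith-Waterman DP oracle", {
  set.seed(37)
  aa <- rownames(blosum62_annot)[1:20]
  for (i in 1:8) {
    a <- paste(sample(aa, sample(20:50, 1), TRUE), collapse = "")
    b <- paste(sample(aa, sample(20:50, 1), TRUE), collapse = "")
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    expect_equal(max(0, Biostrings::score(pa)),
                 sw_score_oracle(a, b, blosum62_annot))
  }
})

test_that("chain_hsps links collinear HSPs across a plausible intron and
          splits at the intron bound", {
  hsp <- function(qs, qe, gs, ge, score = 100) data.frame(
    query_id = "q", scaffold = "s", frame = 1L, strand = "+",
    q_start = qs, q_end = qe, g_start = gs, g_end = ge, score = score,
    identity = 0.9, stringsAsFactors = FALSE)
  # 2-kb gap -> one two-exon model
  two <- rbind(hsp(1, 100, 1000, 1300), hsp(101, 200, 3300, 3600))
  models <- chain_hsps(two)
  expect_length(models, 1L)
  expect_equal(nrow(models[[1]]$exons), 2L)
  expect_equal(models[[1]]$score, 200)
  # 60-kb gap exceeds the 50-kb default -> two single-exon models
  far <- rbind(hsp(1, 100, 1000, 1300), hsp(101, 200, 61300, 61600))
  models2 <- chain_hsps(far)
  expect_length(models2, 2L)
  expect_true(all(vapply(models2, function(m) nrow(m$exons), integer(1))
                  == 1L))
})

test_that("chain score equals exhaustive enumeration over small HSP sets", {
  set.seed(47)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    qs <- sort(sample.int(500, n))
    hsps <- data.frame(
      query_id = "q", scaffold = "s", frame = 1L, strand = "+",
      q_start = qs, q_end = qs + sample.int(60, n),
      g_start = gs <- sort(sample.int(40000, n)) +
        sample(c(0, 30000), n, TRUE),
      score = sample(20:120, n, TRUE), identity = 0.8,
      stringsAsFactors = FALSE)
    hsps$g_end <- hsps$g_start + 3 * (hsps$q_end - hsps$q_start + 1)
    params <- search_params(max_intron = 20000)
    models <- chain_hsps(hsps, params)
    best_impl <- max(vapply(models, `[[`, numeric(1), "score"))
    # enumeration: all subsets, keep collinear ones
    best_oracle <- 0
    for (mask in 1:(2^n - 1)) {
      idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      idx <- idx[order(hsps$q_start[idx])]
      ok <- TRUE
      if (length(idx) > 1) {
        for (k in 2:length(idx)) {
          i <- idx[k]; j <- idx[k - 1]
          gap <- hsps$g_start[i] - hsps$g_end[j]
          if (hsps$q_start[i] <= hsps$q_end[j] || gap < 0 ||
              gap > params$max_intron) { ok <- FALSE; break }
        }
      }
      if (ok) best_oracle <- max(best_oracle, sum(hsps$score[idx]))
    }
    expect_equal(best_impl, best_oracle)
  }
})

test_that("iterate_annotation walks a divergence chain to a fixed point", {
  # three paralogs: seed detects only #1, #1 detects #2, #2 detects #3
  set.seed(57)
  p1 <- chemrep:::random_protein(120)
  p2 <- chemrep:::mutate_protein(p1, 54)   # ~55% identity to p1
  p3 <- chemrep:::mutate_protein(p2, 54)   # ~55% to p2, ~30% to p1
  seed_prot <- chemrep:::mutate_protein(p1, 18)  # 85% identity to p1
  cds <- vapply(c(p1, p2, p3), chemrep:::random_cds_for, character(1))
  genome <- c(scf1 = make_scaffold(cds, c(1000, 3000, 5000), 7000,
                                   seed = 58))
  params <- search_params(min_score = 250)
  # the seed only reaches paralog 1 directly
  direct <- translated_search(c(seed = seed_prot), genome, params)
  direct_loci <- unique(floor(direct$g_start / 1000))
  expect_equal(direct_loci, 1)
  res <- iterate_annotation(c(seed = seed_prot), genome, params)
  expect_equal(nrow(res), 3L)
  expect_equal(sort(floor(res$start / 1000)), c(1, 3, 5))
  rounds <- attr(res, "rounds")
  expect_equal(sum(rounds > 0), 3L)  # one new locus per round
  # fixed point: a further round with the final repertoire adds nothing
  more <- translated_search(setNames(res$protein, res$gene_id), genome,
                            params)
  models <- chain_hsps(more, params)
  spans <- vapply(models, function(m) chemrep:::model_span(m)["start"],
                  numeric(1))
  for (s in spans)
    expect_true(any(abs(s - res$start) < 2000))  # only known loci again
})

test_that("iterate_annotation handles the no-hit case and keeps loci
          disjoint and order-stable", {
  genome <- c(scf1 = strrep("ACGT", 500))
  res <- iterate_annotation(c(seed = strrep("W", 50)), genome,
                            search_params(min_score = 100))
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "rounds"), 0L)

  set.seed(67)
  p1 <- chemrep:::random_protein(100)
  p2 <- chemrep:::mutate_protein(p1, 30)
  cds <- vapply(c(p1, p2), chemrep:::random_cds_for, character(1))
  genome2 <- c(scf1 = make_scaffold(cds, c(500, 2500), 4500, seed = 68))
  params <- search_params(min_score = 150)
  seeds <- c(s1 = p1, s2 = p2)
  r1 <- iterate_annotation(seeds, genome2, params)
  r2 <- iterate_annotation(seeds[c(2, 1)], genome2, params)
  # seed order does not change the accepted repertoire
  expect_equal(r1[, c("scaffold", "start", "end", "strand")],
               r2[, c("scaffold", "start", "end", "strand")])
  # accepted loci are pairwise non-overlapping
  if (nrow(r1) > 1) {
    ord <- order(r1$scaffold, r1$start)
    same <- diff(match(r1$scaffold[ord], unique(r1$scaffold))) == 0
    expect_true(all(r1$start[ord][-1][same] >=
                    r1$end[ord][-nrow(r1)][same]))
  }
})
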