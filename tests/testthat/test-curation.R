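# Curation rules: allele collapse, completeness classification, the
# C-terminal GR-domain motif, summary-table arithmetic, genome sizing.

blosum62 <- local({
  data("BLOSUM62", package = "Biostrings", envir = environment())
  BLOSUM62
})

test_that("pairwise_identity counts identical aligned positions", {
  a <- strrep("MKLVANQWERT", 10)  # 110 aa
  expect_equal(pairwise_identity(a, a), 1.0)
  # 100-mer with 5 substitutions -> 0.95
  base <- paste(rep("A", 100), collapse = "")
  mut <- base
  for (p in c(10, 30, 50, 70, 90)) substr(mut, p, p) <- "W"
  expect_equal(pairwise_identity(base, mut), 0.95)
  expect_error(pairwise_identity("", "MKL"), "nonempty")
})

test_that("pairwise_identity agrees with a Needleman-Wunsch oracle", {
  set.seed(31)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  # on unrelated pairs co-optimal alignments can differ in identity, so
  # compare the (unique) optimal global score against the oracle's
  for (i in 1:12) {
    n1 <- sample(25:45, 1); n2 <- sample(25:45, 1)
    a <- paste(sample(aa, n1, TRUE), collapse = "")
    b <- paste(sample(aa, n2, TRUE), collapse = "")
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(pa),
                 attr(nw_identity_oracle(a, b, blosum62), "score"),
                 tolerance = 1e-9)
  }
  # on near-identical pairs -- where the allele rule operates -- the
  # optimal alignment is unique and identities must agree exactly
  for (i in 1:8) {
    a <- paste(sample(aa, 60, TRUE), collapse = "")
    b <- a
    for (p in sample.int(60, 4)) substr(b, p, p) <- sample(aa, 1)
    expect_equal(pairwise_identity(a, b),
                 as.numeric(nw_identity_oracle(a, b, blosum62)),
                 tolerance = 1e-12)
  }
})

test_that("collapse_alleles keeps the longest member and is
          order-invariant", {
  prots <- make_identity_controlled_proteins(2, 0.95, 400, seed = 5)
  rec <- data.frame(gene_id = c("g1", "g2"),
                    protein = c(prots[[1]],
                                substr(prots[[2]], 1, 380)),
                    category = c("complete", "partial"),
                    stringsAsFactors = FALSE)
  out <- collapse_alleles(rec)
  expect_equal(out$category, c("complete", "allele"))
  expect_equal(out$allele_of, c(NA, "g1"))
  # single record unchanged
  expect_equal(collapse_alleles(rec[1, ])$category, "complete")
  # order invariance
  out2 <- collapse_alleles(rec[2:1, ])
  expect_equal(out2$category[out2$gene_id == "g2"], "allele")
  expect_equal(out2$allele_of[out2$gene_id == "g2"], "g1")
})

test_that("collapse_alleles clusters by single linkage like a brute-force
          enumeration", {
  # 6 records: {a,b,c} chained near 95%, {d,e} at ~92%, f alone
  set.seed(77)
  g1 <- make_identity_controlled_proteins(3, 0.95, 300, seed = 101)
  g2 <- make_identity_controlled_proteins(2, 0.92, 260, seed = 102)
  f <- make_identity_controlled_proteins(1, 1, 280, seed = 103)
  rec <- data.frame(
    gene_id = letters[1:6],
    protein = c(g1[[1]], g1[[2]], g1[[3]], g2[[1]], g2[[2]], f[[1]]),
    category = "complete", stringsAsFactors = FALSE)
  # lengthen one member per cluster so the retained copy is unambiguous
  rec$protein[1] <- paste0(rec$protein[1], "MKLV")
  rec$protein[4] <- paste0(rec$protein[4], "MK")
  out <- collapse_alleles(rec, threshold = 0.90)
  # brute-force single linkage from the full identity matrix
  n <- 6
  idm <- outer(1:n, 1:n, Vectorize(function(i, j)
    pairwise_identity(rec$protein[i], rec$protein[j])))
  adj <- idm >= 0.90
  comp <- seq_len(n)
  for (it in 1:n) for (i in 1:n) for (j in 1:n)
    if (adj[i, j]) comp[c(i, j)] <- min(comp[c(i, j)])
  expected_allele <- vapply(seq_len(n), function(i) {
    cl <- which(comp == comp[i])
    length(cl) > 1 && i != cl[order(-nchar(rec$protein[cl]),
                                    rec$gene_id[cl])][1]
  }, logical(1))
  expect_equal(out$category == "allele", expected_allele)
  # the longest member of a cluster is never an allele
  expect_false(out$category[1] == "allele")
  expect_false(out$category[4] == "allele")
  expect_false(out$category[6] == "allele")
})

test_that("classify_gene applies the stop/start/length rules", {
  mk <- function(len) paste(c("M", rep("K", len - 1)), collapse = "")
  # complete: start + terminal stop + >350 aa
  expect_equal(classify_gene(protein = paste0(mk(360), "*")), "complete")
  # internal stop -> pseudogene regardless of length
  p <- paste0(mk(360), "*")
  substr(p, 100, 100) <- "*"
  expect_equal(classify_gene(protein = p), "pseudogene")
  # boundary: exactly 350 aa is partial (strict inequality)
  expect_equal(classify_gene(protein = paste0(mk(350), "*")), "partial")
  expect_equal(classify_gene(protein = paste0(mk(351), "*")), "complete")
  # missing terminal stop or start -> partial
  expect_equal(classify_gene(protein = mk(360)), "partial")
  expect_equal(classify_gene(protein = paste0("K", mk(360), "*")), "partial")
  # from CDS directly
  cds <- paste0("ATG", strrep("AAA", 360), "TAA")
  expect_equal(classify_gene(cds = cds), "complete")
})

test_that("motif_check finds TYhhhhhQF within the C-terminal window only", {
  pad <- function(n) strrep("G", n)
  hit <- paste0(pad(300), "TYLLLLLQF", pad(20))
  res <- motif_check(hit)
  expect_true(res$found)
  expect_equal(res$position, 301)
  # K is not hydrophobic
  expect_false(motif_check(paste0(pad(300), "TYLKLLLQF", pad(20)))$found)
  # motif planted at position 20 of a 500-aa protein is outside the
  # C-terminal 100-aa window ...
  early <- paste0(pad(19), "TYAVIMWQF", pad(472))
  expect_false(motif_check(early)$found)
  # ... though a full-sequence scan oracle does see it
  expect_true(grepl("TY[AVLIMFWCY]{5}QF", early))
  expect_true(motif_check(early, window = nchar(early))$found)
})

test_that("summarize_repertoire reproduces the category arithmetic", {
  s <- summarize_repertoire(c(complete = 275, partial = 50,
                              pseudogene = 19, allele = 29))
  expect_equal(s$total, 373)
  expect_equal(s$final_count, 325)
  s2 <- summarize_repertoire(c(complete = 172, partial = 106,
                               pseudogene = 22, allele = 117))
  expect_equal(s2$total, 417)
  expect_equal(s2$final_count, 278)
  # from records, and empty input
  rec <- data.frame(category = c("complete", "complete", "allele"))
  expect_equal(summarize_repertoire(rec)$counts[["complete"]], 2)
  z <- summarize_repertoire(data.frame(category = character()))
  expect_equal(z$total, 0)
  expect_equal(z$final_count, 0)
})

test_that("clade_proportion computes percentages of complete+partial", {
  counts <- c(A = 20, B = 65, C = 40, D = 97, E = 7, F = 12, G = 10,
              H = 16, I = 7, J = 16, K = 4)
  tab <- clade_proportion(clade_counts = counts,
                          functional_total = 275 + 50)
  expect_equal(tab$count[tab$clade == "Total"], 294)
  expect_equal(tab$percent[tab$clade == "Total"], 90.5)
  # all records in one clade -> 100.0
  rec <- data.frame(gene_id = c("a", "b"), category = "complete",
                    clade = "A", stringsAsFactors = FALSE)
  expect_equal(clade_proportion(rec)$percent[2], 100.0)
  # clade label on an allele is an error
  bad <- data.frame(gene_id = "x", category = "allele", clade = "A",
                    stringsAsFactors = FALSE)
  expect_error(clade_proportion(bad), "allele")
  # random assignment equals a hand recount
  set.seed(9)
  rnd <- data.frame(gene_id = paste0("g", 1:50),
                    category = sample(c("complete", "partial"), 50, TRUE),
                    clade = sample(LETTERS[1:4], 50, TRUE),
                    stringsAsFactors = FALSE)
  tab2 <- clade_proportion(rnd)
  hand <- table(rnd$clade)
  for (cl in names(hand))
    expect_equal(tab2$count[tab2$clade == cl], unname(hand[cl]))
  expect_equal(tab2$percent[tab2$clade == "Total"],
               round(100 * sum(hand) / 50, 1))
})

test_that("genome_size_from_cytometry scales the standard by the 2C
          fluorescence ratio", {
  expect_equal(genome_size_from_cytometry(100, 100), 328)
  expect_equal(genome_size_from_cytometry(50, 100), 164)
  # inverse of the formula: a 470-Mb genome gives ratio 470/328
  expect_equal(genome_size_from_cytometry(470 / 328 * 80, 80), 470)
  expect_error(genome_size_from_cytometry(-1, 100), "positive")
})
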