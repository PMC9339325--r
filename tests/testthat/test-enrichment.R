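# Region construction, contingency counting, Fisher's exact test and FDR
# correction for the TE locus-overlap enrichment analysis.

test_that("build_query_regions merges clustered flanked genes", {
  # two genes 4 kb apart with 10-kb flanks become one region
  r <- build_query_regions(gintervals("s", c(100000, 105000),
                                      c(101000, 106000)),
                           c(s = 300000))
  expect_equal(nrow(r), 1L)
  expect_equal(r$start, 90000)
  expect_equal(r$end, 116000)
  expect_equal(attr(r, "label"), "query")
})

test_that("universe regions match the bitmap oracle on random genomes", {
  set.seed(13)
  slen <- c(s1 = 200000, s2 = 200000)
  for (rep in 1:10) {
    n <- 50
    genes <- gintervals(sample(names(slen), n, TRUE),
                        st <- sample.int(195000, n, TRUE),
                        st + sample.int(3000, n, TRUE))
    u <- build_universe(genes, slen)
    widened <- gintervals(genes$scaffold, pmax(0, genes$start - 10000),
                          pmin(slen[genes$scaffold], genes$end + 10000))
    oracle <- bitmap_merge_oracle(widened)
    expect_equal(nrow(u), nrow(oracle))
    expect_equal(u$start, oracle$start)
    expect_equal(u$end, oracle$end)
  }
})

test_that("make_contingency classifies universe regions", {
  # 8 disjoint universe regions, 4 of them query, TEs in 3 query + 1 other
  universe <- merge_intervals(gintervals("s", (0:7) * 1000, (0:7) * 1000 + 500))
  query <- universe[1:4, ]
  tes <- gintervals("s", c(100, 1100, 2100, 5100), c(200, 1200, 2200, 5200))
  ct <- make_contingency(universe, query, tes)
  expect_equal(ct$a, 3); expect_equal(ct$b, 1)
  expect_equal(ct$c, 1); expect_equal(ct$d, 3)
  # no TEs at all
  ct0 <- make_contingency(universe, query,
                          gintervals(character(), integer(), integer()))
  expect_equal(ct0$a, 0); expect_equal(ct0$b, 0)
  expect_equal(ct0$c, 4); expect_equal(ct0$d, 4)
  # query region outside the universe is an error
  expect_error(make_contingency(universe, gintervals("s", 50000, 51000),
                                tes), "no universe region")
  # margins conserved on random placements vs a per-region recount
  set.seed(21)
  for (rep in 1:10) {
    tes_r <- gintervals("s", st <- sample.int(8000, 30, TRUE),
                        st + sample.int(300, 30, TRUE))
    ct_r <- make_contingency(universe, query, tes_r)
    hand_hit <- vapply(seq_len(nrow(universe)), function(i)
      any(tes_r$start < universe$end[i] & universe$start[i] < tes_r$end),
      logical(1))
    expect_equal(ct_r$a + ct_r$c, 4)
    expect_equal(ct_r$a + ct_r$b + ct_r$c + ct_r$d, 8)
    expect_equal(ct_r$a, sum(hand_hit[1:4]))
    expect_equal(ct_r$b, sum(hand_hit[5:8]))
  }
})

test_that("fisher_exact equals hypergeometric enumeration, including the
          worked 4x4-margin example", {
  # (3,1,1,3): P(X >= 3 | margins 4,4,8) = (16 + 1)/70
  ft <- fisher_exact(list(a = 3, b = 1, c = 1, d = 3))
  expect_equal(ft$p_value, 17 / 70, tolerance = 1e-12)
  expect_equal(ft$odds_ratio, 9)
  # no overlaps anywhere -> p = 1
  expect_equal(fisher_exact(list(a = 0, b = 0, c = 5, d = 10))$p_value, 1)
  # infinite odds ratio when bc = 0 with signal
  expect_equal(fisher_exact(list(a = 2, b = 0, c = 1, d = 5))$odds_ratio,
               Inf)
})

test_that("fisher_exact matches the enumeration oracle for all margins
          up to 12 (exhaustive)", {
  worst <- 0
  for (a in 0:12) for (b in 0:(12 - a)) for (c in 0:(12 - a)) {
    for (d in 0:(12 - max(b, c))) {
      p <- fisher_exact(list(a = a, b = b, c = c, d = d))$p_value
      po <- hyper_p_oracle(a, b, c, d)
      worst <- max(worst, abs(p - min(1, po)))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("bh_fdr performs the step-up adjustment", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  # q >= p elementwise, ordering preserved
  set.seed(3)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_equal(order(q[order(p)]), seq_len(50))
})

test_that("storey_qvalue scales BH by the estimated null proportion", {
  set.seed(4)
  p <- c(runif(150), rbeta(50, 0.2, 4))
  q <- storey_qvalue(p)
  pi0 <- min(1, mean(p > 0.5) / 0.5)
  expect_equal(q, pmin(1, pi0 * bh_fdr(p)))
  expect_true(all(q <= bh_fdr(p) + 1e-12))
  # fdr_qvalue switches on test count
  expect_equal(fdr_qvalue(p[1:20]), bh_fdr(p[1:20]))
  expect_equal(fdr_qvalue(p), storey_qvalue(p))
})

test_that("enrichment_scan returns an empty result without TEs and a
          ranked table otherwise", {
  slen <- c(s1 = 100000)
  fam <- gintervals("s1", 40000, 41000)
  all_genes <- gintervals("s1", c(10000, 40000, 70000),
                          c(11000, 41000, 71000))
  empty <- enrichment_scan(fam, all_genes,
                           data.frame(), slen)
  expect_s3_class(empty, "enrichment_scan")
  expect_equal(nrow(empty), 0L)
  tes <- gintervals("s1", c(39000, 9000), c(39500, 9500))
  tes$family_id <- c("SINE_1", "SINE_1")
  tes$order <- "SINE"
  res <- enrichment_scan(fam, all_genes, tes, slen)
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(res$a + res$b + res$c + res$d == attr(res, "n_universe")))
})
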