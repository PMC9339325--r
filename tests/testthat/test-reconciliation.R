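# LCA mapping and duplication-loss parsimony reconciliation.

two_sp <- ape::read.tree(text = "(A,B);")
pm2 <- c(A_ = "A", B_ = "B")

test_that("lca_map maps leaves to species and internal nodes to LCAs", {
  # congruent single-copy tree: natural isomorphism
  gt <- ape::read.tree(text = "((A_g1,B_g1),C_g1);")
  st <- ape::read.tree(text = "((A,B),C);")
  pm <- c(A_ = "A", B_ = "B", C_ = "C")
  M <- lca_map(gt, st, pm)
  lab <- attr(M, "species_labels")
  expect_equal(lab[M[1:3]], c("A", "B", "C"))
  # root -> species root; (A_g1,B_g1) node -> AB ancestor
  expect_equal(unname(M[4]), 4L)  # species root is node 4 in a 3-tip tree
  expect_equal(unname(M[5]), 5L)
  # duplicated family: ((a1,b1),(a2,b2)) maps root and both children to AB
  gt2 <- ape::read.tree(text = "((A_g1,B_g1),(A_g2,B_g2));")
  M2 <- lca_map(gt2, two_sp, pm2)
  expect_equal(unname(M2[5:7]), c(3L, 3L, 3L))
  # unmapped leaf errors
  expect_error(lca_map(ape::read.tree(text = "(X_g1,A_g1);"), two_sp, pm2),
               "no prefix")
  # non-binary gene tree rejected (internal polytomy)
  poly <- ape::read.tree(text = "((A_g1,A_g2,B_g1),B_g2);")
  expect_error(lca_map(poly, two_sp, pm2), "binary")
  # unrooted input rejected
  expect_error(lca_map(ape::read.tree(text = "(A_g1,A_g2,B_g1);"),
                       two_sp, pm2), "rooted")
})

test_that("lca_map satisfies the ancestor property on random gene trees", {
  st <- ape::read.tree(text = "((A,B),(C,D));")
  pm <- c(A_ = "A", B_ = "B", C_ = "C", D_ = "D")
  sp_par <- chemrep:::phylo_parents(st)
  sp_dep <- chemrep:::phylo_depths(st, sp_par)
  set.seed(19)
  for (rep in 1:25) {
    nl <- sample(3:8, 1)
    species <- sample(c("A", "B", "C", "D"), nl, TRUE)
    gt <- ape::rtree(nl, br = NULL)
    gt$tip.label <- paste0(species, "_g", seq_len(nl))
    M <- lca_map(gt, st, pm)
    gk <- chemrep:::phylo_children(gt)
    for (v in seq_along(gk)) {
      for (ch in gk[[v]]) {
        expect_true(chemrep:::is_ancestor_or_equal(M[v], M[ch], sp_par,
                                                   sp_dep))
      }
    }
  }
})

test_that("reconcile reproduces hand-computed duplication/loss scenarios", {
  # ((a1,b1),(a2,b2)) on (A,B): one duplication at the AB ancestor, no loss
  gt <- ape::read.tree(text = "((A_g1,B_g1),(A_g2,B_g2));")
  r <- reconcile(gt, two_sp, pm2)
  expect_equal(length(r$duplications), 1L)
  expect_equal(sum(r$losses), 0L)
  expect_equal(r$dl_cost, 1L)
  expect_equal(unname(r$gains[attr(r$node_map, "species_labels")[3]]), 1L)
  # lineages: 2 entering each extant species
  expect_equal(unname(r$ancestral_count[c("A", "B")]), c(2L, 2L))
  # (a1,(a2,b1)) on (A,B): 1 duplication, 1 loss on the B branch
  gt2 <- ape::read.tree(text = "(A_g1,(A_g2,B_g1));")
  r2 <- reconcile(gt2, two_sp, pm2)
  expect_equal(length(r2$duplications), 1L)
  expect_equal(sum(r2$losses), 1L)
  expect_equal(unname(r2$losses["B"]), 1L)
  expect_equal(r2$dl_cost, 2L)
  expect_equal(unname(r2$ancestral_count[c("A", "B")]), c(2L, 1L))
})

test_that("self-reconciliation yields zero duplications and losses", {
  st <- ape::read.tree(text = "(((A,B),C),(D,E));")
  gt <- ape::read.tree(text = "(((A_g1,B_g1),C_g1),(D_g1,E_g1));")
  pm <- setNames(st$tip.label, paste0(st$tip.label, "_"))
  r <- reconcile(gt, st, pm)
  expect_equal(length(r$duplications), 0L)
  expect_equal(sum(r$losses), 0L)
  expect_equal(r$dl_cost, 0L)
  expect_true(all(r$ancestral_count == 1L))
})

test_that("dl_cost is parsimony-minimal against the exhaustive mapping
          oracle on random instances", {
  st <- ape::read.tree(text = "((A,B),C);")
  pm <- c(A_ = "A", B_ = "B", C_ = "C")
  set.seed(23)
  for (rep in 1:30) {
    nl <- sample(2:5, 1)
    species <- sample(c("A", "B", "C"), nl, TRUE)
    gt <- ape::rtree(nl, br = NULL)
    gt$tip.label <- paste0(species, "_g", seq_len(nl))
    r <- reconcile(gt, st, pm)
    expect_equal(r$dl_cost, recon_cost_oracle(gt, st, pm))
  }
})

test_that("per-branch conservation identity holds and leaf counts equal
          repertoire sizes on simulated birth-death families", {
  st <- ape::read.tree(text = "((A:1,B:1):0.6,(C:0.8,D:0.8):0.8);")
  set.seed(1)
  for (rep in 1:25) {
    sim <- simulate_gene_family(
      family_sim_config(st, lambda = 0.4, mu = 0.2, seed = 1000 + rep))
    r <- reconcile(sim$gene_tree, st, sim$prefix_map)
    ev <- r$events
    sp_par <- chemrep:::phylo_parents(st)
    for (i in seq_len(nrow(ev))) {
      par <- sp_par[i]
      if (is.na(par)) next
      expect_equal(ev$count[i], ev$count[par] + ev$gains[i] - ev$losses[i])
    }
    # leaves carry the observed per-species gene counts
    obs <- table(factor(chemrep::species_of_leaf(sim$gene_tree$tip.label,
                                                 sim$prefix_map),
                        levels = st$tip.label))
    expect_equal(unname(r$ancestral_count[st$tip.label]),
                 as.integer(obs))
    # parsimony cost never exceeds the true event count
    expect_lte(r$dl_cost, sum(sim$truth$gains) + sum(sim$truth$losses))
  }
})

test_that("loss-free simulations are exactly recovered", {
  st <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  set.seed(2)
  for (rep in 1:15) {
    sim <- simulate_gene_family(
      family_sim_config(st, lambda = 0.5, mu = 0, seed = 2000 + rep))
    r <- reconcile(sim$gene_tree, st, sim$prefix_map)
    expect_equal(sum(r$losses), 0L)
    # per-branch duplication counts match the truth exactly
    truth <- sim$truth
    for (i in seq_len(nrow(truth))) {
      expect_equal(unname(r$gains[truth$species_node[i]]),
                   truth$gains[i])
    }
  }
})

test_that("no-event simulations give the congruent single-copy tree", {
  st <- ape::read.tree(text = "((A:1,B:1):0.5,C:1.5);")
  sim <- simulate_gene_family(family_sim_config(st, 0, 0, seed = 5))
  expect_equal(sort(sim$gene_tree$tip.label),
               c("A_g1", "B_g1", "C_g1"))
  expect_true(all(sim$truth$gains == 0L))
  expect_true(all(sim$truth$losses == 0L))
  r <- reconcile(sim$gene_tree, st, sim$prefix_map)
  expect_equal(r$dl_cost, 0L)
})
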