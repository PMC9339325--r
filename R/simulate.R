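# Seed-deterministic generators: a synthetic genome with tandem-duplicated
# gene clusters (alleles, pseudogenes, boundary-truncated partials) and TE
# insertions with controllable near-cluster enrichment; birth-death gene
# families on a species tree; identity-controlled protein sets. Every
# generator emits machine-readable truth tables.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

# one random CDS coding the given protein (uniform over synonymous codons)
random_cds_for <- function(protein) {
  u <- codon_universe()
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- u$codons[u$aa == a]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

random_protein <- function(len) {
  paste(c("M", sample(AA20, len - 1L, replace = TRUE)), collapse = "")
}

# substitute n_changes positions; the initiator Met (position 1) is never
# touched so completeness calls on mutated variants stay meaningful
mutate_protein <- function(protein, n_changes, positions = NULL) {
  aa <- strsplit(protein, "")[[1]]
  if (is.null(positions))
    positions <- sample(seq(2L, length(aa)), min(n_changes, length(aa) - 1L))
  for (p in positions) aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
  paste(aa, collapse = "")
}

#' Configuration for the synthetic genome generator
#'
#' Defaults describe a desk-scale polyphagous-moth-like setting: a 5-Mb
#' genome carrying 30 tandem clusters of receptor genes (3 genes each, ~10%
#' of loci) among ~470 background genes, with TE families at realistic
#' copy numbers and a designated family enriched near the clusters.
#'
#' @param n_scaffolds,scaffold_length genome layout (bp).
#' @param n_clusters,genes_per_cluster receptor-family clusters.
#' @param n_background_genes other genic loci (enrichment universe).
#' @param background_gene_length bp length of background gene loci
#'   (default 2000; set it to the receptor gene footprint,
#'   `3 * (protein_length + 1)`, when the enrichment null needs query and
#'   background windows of identical width).
#' @param protein_length receptor protein length in aa (> 350 so intact
#'   genes are complete).
#' @param paralog_divergence aa substitutions per site between cluster
#'   paralogs (default 0.3, comfortably above the 90% allele band).
#' @param allele_rate probability a receptor gene carries an allelic copy.
#' @param allele_identity protein identity of allelic copies (>= 0.9).
#' @param pseudogene_rate probability of internal-stop injection.
#' @param truncation_rate probability a cluster-edge gene is cut by a
#'   scaffold boundary (partial gene phenomenon).
#' @param te_families named numeric vector: background TE density per kb
#'   for each family.
#' @param te_orders named character vector: TE order per family (same
#'   names).
#' @param enrichment named numeric vector of per-family near-cluster
#'   enrichment factors (families absent default to 1).
#' @param cluster_flank half-width of the near-cluster window, bp.
#' @param gene_spacing spacing between genes inside a cluster, bp.
#' @param min_gene_separation minimum bp between distinct gene loci
#'   (cluster footprints count as one locus). Setting this above
#'   `2 * cluster_flank + gene length` prevents flanked windows from
#'   merging, which makes query and universe regions exchangeable -- the
#'   homogeneous geometry needed for honest type-I-error calibration of
#'   the enrichment test.
#' @param emit_sequence build the scaffold nucleotide sequences (skip for
#'   interval-only consumers such as the enrichment tests; truth tables and
#'   coordinates are produced either way).
#' @param seed RNG seed (mandatory).
#' @return list of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_scaffolds = 40L, scaffold_length = 500000L,
                              n_clusters = 30L, genes_per_cluster = 3L,
                              n_background_genes = 470L,
                              background_gene_length = 2000L,
                              protein_length = 400L,
                              paralog_divergence = 0.3,
                              allele_rate = 0.08, allele_identity = 0.95,
                              pseudogene_rate = 0.05,
                              truncation_rate = 0.1,
                              te_families = c(SINE_1 = 0.015,
                                              LINE_1 = 0.015,
                                              LTR_1 = 0.015,
                                              TIR_1 = 0.015,
                                              Helitron_1 = 0.015,
                                              MITE_1 = 0.015),
                              te_orders = c(SINE_1 = "SINE",
                                            LINE_1 = "LINE",
                                            LTR_1 = "LTR", TIR_1 = "TIR",
                                            Helitron_1 = "Helitron",
                                            MITE_1 = "MITE"),
                              enrichment = c(SINE_1 = 1),
                              cluster_flank = 10000L,
                              gene_spacing = 4000L,
                              min_gene_separation = 0L,
                              emit_sequence = TRUE,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  rates <- c(allele_rate, allele_identity, pseudogene_rate, truncation_rate,
             paralog_divergence)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (any(te_families < 0)) stop("TE densities must be >= 0")
  if (any(enrichment < 0)) stop("enrichment factors must be >= 0")
  miss <- setdiff(names(te_families), names(te_orders))
  if (length(miss)) stop("no TE order for: ", paste(miss, collapse = ", "))
  structure(as.list(environment()), class = "genome_sim_config")
}

#' TE order to class mapping
#'
#' Class I retrotransposons: DIRS, LARD, LINE, LTR, PLE, SINE, TRIM;
#' class II DNA transposons: Helitron, MITE, Maverick, TIR; everything
#' else is `noCat`.
#'
#' @param order character vector of TE orders.
#' @return character vector `"I"`, `"II"` or `"noCat"`.
#' @export
te_class_of_order <- function(order) {
  class1 <- c("DIRS", "LARD", "LINE", "LTR", "PLE", "SINE", "TRIM")
  class2 <- c("Helitron", "MITE", "Maverick", "TIR")
  ifelse(order %in% class1, "I", ifelse(order %in% class2, "II", "noCat"))
}

#' Simulate a genome with receptor clusters, alleles, pseudogenes and TEs
#'
#' Plants tandem clusters of receptor genes (diverged paralogs of a common
#' ancestor), allelic near-duplicates, internal-stop pseudogenes and
#' scaffold-boundary-truncated partial genes into random scaffolds;
#' scatters background genes (the enrichment universe); and drops TE
#' copies from a Poisson process whose intensity is multiplied by the
#' per-family enrichment factor inside the near-cluster windows. Identical
#' seeds give identical output.
#'
#' @param config a [genome_sim_config()].
#' @return list with `genome` (named scaffold sequences), `genes`
#'   (intervals of receptor genes, with `gene_id`), `all_genes` (receptor +
#'   background gene intervals), `tes` (TE intervals with `family_id`,
#'   `order`, `te_class`), `truth_genes` (per planted gene: true
#'   `category`, `allele_of`, `clade`, `cluster`, `protein`, `cds`,
#'   `at_scaffold_boundary`), `truth_tes`, `scaffold_lengths`, `config`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "genome_sim_config"))
  set.seed(config$seed)
  nsc <- config$n_scaffolds
  slen <- rep_len(config$scaffold_length, nsc)
  scaffolds <- sprintf("scf%02d", seq_len(nsc))
  scaffold_lengths <- stats::setNames(slen, scaffolds)

  # -- receptor clusters ------------------------------------------------------
  clades <- LETTERS[1:11]
  genes <- list(); truth <- list(); planted_seq <- list()
  gid <- 0L
  glen_bp <- function(p) 3L * (nchar(p) + 1L)  # CDS + stop
  cluster_scaffold <- sample(scaffolds, config$n_clusters, replace = TRUE)
  cluster_spans <- list()  # per scaffold: matrix of (start, end) taken
  for (cl in seq_len(config$n_clusters)) {
    sc <- cluster_scaffold[cl]
    base <- random_protein(config$protein_length)
    clade <- sample(clades, 1L)
    npara <- config$genes_per_cluster
    # worst case: every gene also carries an allele copy
    span_needed <- 2L * npara * (glen_bp(base) + config$gene_spacing) + 2000L
    sep <- config$min_gene_separation
    taken <- cluster_spans[[sc]]
    anchor <- NA_integer_
    for (try in 1:100) {
      cand <- sample.int(max(1L, scaffold_lengths[[sc]] - span_needed), 1L)
      clash <- !is.null(taken) &&
        any(cand - sep < taken[, 2] & taken[, 1] < cand + span_needed + sep)
      if (!clash) { anchor <- cand; break }
    }
    if (is.na(anchor)) next  # scaffold too crowded; skip this cluster
    cluster_spans[[sc]] <- rbind(taken, c(anchor, anchor + span_needed))
    pos <- anchor
    truncate_here <- stats::runif(1) < config$truncation_rate
    for (g in seq_len(npara)) {
      gid <- gid + 1L
      nmut <- stats::rbinom(1, nchar(base), config$paralog_divergence)
      prot <- mutate_protein(base, nmut)
      category <- "complete"
      if (stats::runif(1) < config$pseudogene_rate) category <- "pseudogene"
      cds <- paste0(random_cds_for(prot), "TAA")
      if (category == "pseudogene") {
        # inject 1-2 premature stops
        aa_stop <- sort(sample(seq(10L, nchar(prot) - 10L),
                               sample(1:2, 1)))
        for (p in aa_stop)
          substr(cds, 3L * p - 2L, 3L * p) <- "TAA"
      }
      id <- sprintf("GR%03d", gid)
      start <- pos
      end <- start + nchar(cds)
      at_boundary <- FALSE
      if (truncate_here && g == npara) {
        # cut the scaffold mid-gene: keep the 5' 60% of the CDS
        keep <- 3L * floor(0.6 * nchar(prot))
        cds <- substr(cds, 1L, keep)
        end <- start + keep
        at_boundary <- TRUE
        if (category != "pseudogene") category <- "partial"
      }
      genes[[id]] <- data.frame(scaffold = sc, start = start, end = end,
                                strand = "+", gene_id = id,
                                stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(
        gene_id = id, category = category, allele_of = NA_character_,
        clade = clade, cluster = cl, at_scaffold_boundary = at_boundary,
        protein = translate_cds(cds), cds = cds, stringsAsFactors = FALSE)
      planted_seq[[id]] <- list(scaffold = sc, start = start, cds = cds)
      pos <- end + config$gene_spacing
      # allelic copy of a clean gene, appended after the cluster genes
      if (category == "complete" &&
          stats::runif(1) < config$allele_rate) {
        gid <- gid + 1L
        nmut_a <- max(1L, round((1 - config$allele_identity) *
                                  nchar(prot) * 19 / 18))
        aprot <- mutate_protein(prot, nmut_a)
        # alleles are shorter so the primary copy is retained at collapse
        aprot <- substr(aprot, 1L, nchar(aprot) - 5L)
        acds <- paste0(random_cds_for(aprot), "TAA")
        aid <- sprintf("GR%03d", gid)
        astart <- pos
        aend <- astart + nchar(acds)
        genes[[aid]] <- data.frame(scaffold = sc, start = astart,
                                   end = aend, strand = "+", gene_id = aid,
                                   stringsAsFactors = FALSE)
        truth[[aid]] <- data.frame(
          gene_id = aid, category = "allele", allele_of = id,
          clade = clade, cluster = cl, at_scaffold_boundary = FALSE,
          protein = translate_cds(acds), cds = acds,
          stringsAsFactors = FALSE)
        planted_seq[[aid]] <- list(scaffold = sc, start = astart,
                                   cds = acds)
        pos <- aend + config$gene_spacing
      }
    }
  }
  genes <- do.call(rbind, genes)
  truth <- do.call(rbind, truth)
  rownames(genes) <- rownames(truth) <- NULL

  # scaffold-boundary truncation: clip each truncated gene's scaffold just
  # after the cut gene (only when nothing else lies beyond it)
  for (i in which(truth$at_scaffold_boundary)) {
    sc <- genes$scaffold[i]; cut <- genes$end[i]
    beyond <- genes$scaffold == sc & genes$end > cut
    if (!any(beyond)) scaffold_lengths[[sc]] <- cut
  }

  # -- background genes (batch placement with overlap rejection) --------------
  bg_len <- as.integer(config$background_gene_length)
  occupied <- genes[, c("scaffold", "start", "end", "strand", "gene_id")]
  placed <- list()
  n_placed <- 0L
  for (batch in 1:30) {
    need <- config$n_background_genes - n_placed
    if (need <= 0L) break
    sc <- sample(scaffolds, 2L * need, replace = TRUE)
    ok_len <- scaffold_lengths[sc] > bg_len + 2L
    sc <- sc[ok_len]
    if (!length(sc)) next
    sep <- config$min_gene_separation
    lo <- sep
    hi <- scaffold_lengths[sc] - bg_len - 1L - sep
    ok2 <- hi > lo
    sc <- sc[ok2]
    if (!length(sc)) next
    start <- floor(stats::runif(length(sc), lo, hi[ok2]))
    cand <- gintervals(sc, start, start + bg_len)
    # drop candidates clashing (within the separation margin) with
    # occupied loci or earlier candidates
    grown <- function(x) gintervals(x$scaffold, pmax(0, x$start - sep),
                                    x$end + sep)
    clash <- overlaps_any(grown(cand), occupied)
    keep <- logical(nrow(cand))
    for (i in order(cand$scaffold, cand$start)) {
      if (clash[i]) next
      prev <- which(keep & cand$scaffold == cand$scaffold[i] &
                      cand$start - sep < cand$end[i] + sep &
                      cand$end + sep > cand$start[i] - sep)
      if (!length(prev)) keep[i] <- TRUE
    }
    sel <- which(keep)[seq_len(min(need, sum(keep)))]
    if (!length(sel)) next
    got <- cand[sel, , drop = FALSE]
    got$gene_id <- sprintf("bg%04d", n_placed + seq_along(sel))
    placed[[batch]] <- got
    occupied <- rbind(occupied, got)
    n_placed <- n_placed + length(sel)
  }
  bg <- do.call(rbind, placed)
  all_genes <- rbind(genes[, c("scaffold", "start", "end", "strand",
                               "gene_id")], bg)
  all_genes <- all_genes[order(all_genes$scaffold, all_genes$start), ]
  rownames(all_genes) <- NULL

  # -- TE placement: piecewise-constant Poisson intensity ---------------------
  cluster_windows <- flank_and_merge(genes, scaffold_lengths,
                                     flank = config$cluster_flank)
  te_len <- function(order) switch(order, SINE = 300L, LINE = 2000L,
                                   LTR = 1500L, TIR = 800L,
                                   Helitron = 1000L, MITE = 400L, 500L)
  tes <- list()
  for (fam in names(config$te_families)) {
    dens <- config$te_families[[fam]] / 1000   # per bp
    enr <- if (fam %in% names(config$enrichment))
      config$enrichment[[fam]] else 1
    ord <- config$te_orders[[fam]]
    for (sc in scaffolds) {
      L <- scaffold_lengths[[sc]]
      win <- cluster_windows[cluster_windows$scaffold == sc, , drop = FALSE]
      # near-cluster segments at dens * enr, remainder at dens
      inside <- if (nrow(win)) sum(win$end - win$start) else 0
      n_in <- stats::rpois(1, dens * enr * inside)
      n_out <- stats::rpois(1, dens * (L - inside))
      starts <- numeric(0)
      if (n_in > 0 && inside > 0) {
        # uniform over the union of cluster windows
        off <- sort(stats::runif(n_in, 0, inside))
        cum <- c(0, cumsum(win$end - win$start))
        seg <- findInterval(off, cum, rightmost.closed = TRUE)
        starts <- c(starts, win$start[seg] + (off - cum[seg]))
      }
      if (n_out > 0 && L > inside) {
        # rejection-sample the complement
        got <- numeric(0)
        while (length(got) < n_out) {
          cand <- stats::runif(2L * (n_out - length(got)), 0, L)
          if (nrow(win)) {
            hit <- vapply(cand, function(x)
              any(x >= win$start & x < win$end), logical(1))
            cand <- cand[!hit]
          }
          got <- c(got, cand)
        }
        starts <- c(starts, got[seq_len(n_out)])
      }
      if (!length(starts)) next
      starts <- floor(starts)
      ends <- pmin(L, starts + te_len(ord))
      keep <- ends > starts
      if (!any(keep)) next
      tes[[length(tes) + 1L]] <- data.frame(
        scaffold = sc, start = starts[keep], end = ends[keep],
        strand = ".", family_id = fam, order = ord,
        te_class = te_class_of_order(ord), stringsAsFactors = FALSE)
    }
  }
  tes <- if (length(tes)) do.call(rbind, tes) else
    data.frame(scaffold = character(), start = numeric(), end = numeric(),
               strand = character(), family_id = character(),
               order = character(), te_class = character(),
               stringsAsFactors = FALSE)
  tes <- tes[order(tes$scaffold, tes$start), ]
  rownames(tes) <- NULL

  # -- scaffold sequences with planted gene CDSs ------------------------------
  genome <- NULL
  if (config$emit_sequence) {
    genome <- stats::setNames(vector("character", nsc), scaffolds)
    for (sc in scaffolds) {
      L <- scaffold_lengths[[sc]]
      genome[[sc]] <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                            collapse = "")
    }
    for (ps in planted_seq) {
      L <- scaffold_lengths[[ps$scaffold]]
      cds <- ps$cds
      end <- min(ps$start + nchar(cds), L)
      substr(genome[[ps$scaffold]], ps$start + 1L, end) <-
        substr(cds, 1L, end - ps$start)
    }
  }

  list(genome = genome, genes = genes, all_genes = all_genes, tes = tes,
       truth_genes = truth, truth_tes = tes,
       scaffold_lengths = scaffold_lengths,
       cluster_windows = cluster_windows, config = config)
}

#' Configuration for the birth-death gene-family simulator
#'
#' @param species_tree rooted binary `ape::phylo` with branch lengths.
#' @param lambda per-lineage duplication rate.
#' @param mu per-lineage loss rate.
#' @param root_copies gene copies entering the species root.
#' @param seed RNG seed (mandatory).
#' @export
family_sim_config <- function(species_tree, lambda, mu, root_copies = 1L,
                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(lambda >= 0, mu >= 0, root_copies >= 1)
  check_binary_rooted(species_tree, "species tree")
  structure(list(species_tree = species_tree, lambda = lambda, mu = mu,
                 root_copies = root_copies, seed = seed),
            class = "family_sim_config")
}

#' Simulate a gene family by birth-death along a species tree
#'
#' Each gene lineage duplicates at rate `lambda` and dies at rate `mu`
#' along every species branch; at speciations surviving lineages enter both
#' child branches. The surviving-lineage gene tree is returned with leaves
#' named `<species>_g<i>`, together with the true per-branch duplication
#' and loss counts (keyed by the species node each branch leads into). If
#' fewer than two gene copies survive, the replicate is resampled with an
#' incremented seed (recorded in `resamples`).
#'
#' @param config a [family_sim_config()].
#' @param max_resamples bound on extinction resampling.
#' @return list with `gene_tree` (`ape::phylo`), `truth` (data.frame
#'   `species_node`, `gains`, `losses`), `prefix_map`, `resamples`.
#' @export
simulate_gene_family <- function(config, max_resamples = 100L) {
  stopifnot(inherits(config, "family_sim_config"))
  sp <- config$species_tree
  sp_parent <- phylo_parents(sp)
  sp_kids <- phylo_children(sp)
  sp_root <- which(is.na(sp_parent))
  lab <- species_node_labels(sp)
  edge_len <- function(child) sp$edge.length[match(child, sp$edge[, 2])]

  for (attempt in 0:max_resamples) {
    set.seed(config$seed + attempt)
    gains <- stats::setNames(rep(0L, length(lab)), lab)
    losses <- gains
    leaf_n <- stats::setNames(rep(0L, ape::Ntip(sp)), sp$tip.label)
    lam <- config$lambda; mu <- config$mu
    # simulate one lineage from the top of the branch into species node s;
    # returns a newick fragment or NULL if it leaves no surviving descendant
    descend <- function(s, time_left) {
      repeat {
        total <- lam + mu
        wait <- if (total > 0) stats::rexp(1, total) else Inf
        if (wait < time_left) {
          time_left <- time_left - wait
          if (stats::runif(1) < lam / total) {
            gains[lab[s]] <<- gains[lab[s]] + 1L
            a <- descend(s, time_left)
            b <- descend(s, time_left)
            if (is.null(a)) return(b)
            if (is.null(b)) return(a)
            return(paste0("(", a, ",", b, ")"))
          } else {
            losses[lab[s]] <<- losses[lab[s]] + 1L
            return(NULL)
          }
        } else break
      }
      # reached species node s
      if (s <= ape::Ntip(sp)) {
        leaf_n[lab[s]] <<- leaf_n[lab[s]] + 1L
        return(paste0(lab[s], "_g", leaf_n[lab[s]]))
      }
      ch <- sp_kids[[s]]
      a <- descend(ch[1], edge_len(ch[1]))
      b <- descend(ch[2], edge_len(ch[2]))
      if (is.null(a)) return(b)
      if (is.null(b)) return(a)
      paste0("(", a, ",", b, ")")
    }
    roots <- vector("list", config$root_copies)
    for (r in seq_len(config$root_copies))
      roots[[r]] <- descend(sp_root, 0)
    roots <- Filter(Negate(is.null), roots)
    frag <- if (length(roots) == 0L) NULL
            else if (length(roots) == 1L) roots[[1]]
            else Reduce(function(a, b) paste0("(", a, ",", b, ")"), roots)
    nleaf <- sum(leaf_n)
    if (!is.null(frag) && nleaf >= 2L) {
      tree <- ape::read.tree(text = paste0(frag, ";"))
      truth <- data.frame(species_node = lab, gains = unname(gains[lab]),
                          losses = unname(losses[lab]),
                          stringsAsFactors = FALSE)
      pm <- stats::setNames(sp$tip.label, paste0(sp$tip.label, "_"))
      return(list(gene_tree = tree, truth = truth, prefix_map = pm,
                  resamples = attempt))
    }
  }
  stop("family went extinct in every resampling attempt")
}

#' Generate a protein set with controlled pairwise identity
#'
#' All `n` sequences are independently mutated copies of a hidden ancestor
#' at a shared set of variable positions, calibrated so every pairwise
#' identity is close to `target_identity` (within about +/- 0.02 for
#' typical lengths).
#'
#' @param n number of sequences.
#' @param target_identity desired pairwise identity in `[0, 1]`.
#' @param length protein length in aa.
#' @param seed RNG seed (mandatory).
#' @return named character vector `prot1..protn`.
#' @export
make_identity_controlled_proteins <- function(n, target_identity, length,
                                              seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n >= 1, target_identity >= 0, target_identity <= 1,
            length >= 10)
  k <- round((1 - target_identity) * length * 19 / 18)
  if (k > length)
    stop("infeasible target identity for this length")
  set.seed(seed)
  base <- random_protein(length)
  sites <- if (k > 0) sample(seq(2L, length), min(k, length - 1L))
           else integer(0)
  out <- vapply(seq_len(n), function(i) {
    if (k == 0) base else mutate_protein(base, k, positions = sites)
  }, character(1))
  stats::setNames(out, paste0("prot", seq_len(n)))
}
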