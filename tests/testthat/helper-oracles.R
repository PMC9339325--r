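# Independent oracles used across the suite. These deliberately use naive
# brute-force formulations (bitmaps, quadratic DP, exhaustive enumeration)
# so they share no code path with the package implementations they check.

# union of intervals on one scaffold via a base-pair bitmap
bitmap_merge_oracle <- function(intervals) {
  out <- list()
  for (sc in sort(unique(intervals$scaffold))) {
    p <- intervals[intervals$scaffold == sc, , drop = FALSE]
    L <- max(p$end)
    bit <- rep(FALSE, L)
    for (i in seq_len(nrow(p))) bit[seq(p$start[i] + 1L, p$end[i])] <- TRUE
    r <- rle(bit)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    if (any(keep))
      out[[sc]] <- data.frame(scaffold = sc, start = starts[keep],
                              end = ends[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# bitmap overlap of two single intervals
bitmap_overlap_oracle <- function(a, b) {
  if (a$scaffold != b$scaffold) return(FALSE)
  L <- max(a$end, b$end)
  x <- rep(FALSE, L); y <- rep(FALSE, L)
  x[seq(a$start + 1L, a$end)] <- TRUE
  y[seq(b$start + 1L, b$end)] <- TRUE
  any(x & y)
}

# quadratic affine-gap Smith-Waterman score (no package code)
sw_score_oracle <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)     # match state
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (consume a)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (consume b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[a[i - 1], b[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1],
                                Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
      best <- max(best, M[i, j])
    }
  }
  best
}

# global Needleman-Wunsch (Gotoh affine) alignment returning identity over
# non-gap-pair columns; gap of length g costs gap_open + gap_extend * g
nw_identity_oracle <- function(a, b, submat, gap_open = 10,
                               gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  ptrM <- matrix(1L, n + 1, m + 1); ptrX <- matrix(1L, n + 1, m + 1)
  ptrY <- matrix(1L, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) {
    X[i, 1] <- -gap_open - gap_extend * (i - 1)
    ptrX[i, 1] <- if (i == 2) 1L else 2L
  }
  if (m >= 1) for (j in 2:(m + 1)) {
    Y[1, j] <- -gap_open - gap_extend * (j - 1)
    ptrY[1, j] <- if (j == 2) 1L else 3L
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      cand <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- which.max(cand)
      M[i, j] <- s + cand[k]; ptrM[i, j] <- k
      candX <- c(M[i - 1, j] - gap_open - gap_extend,
                 X[i - 1, j] - gap_extend)
      kX <- which.max(candX)
      X[i, j] <- candX[kX]; ptrX[i, j] <- c(1L, 2L)[kX]
      candY <- c(M[i, j - 1] - gap_open - gap_extend,
                 Y[i, j - 1] - gap_extend)
      kY <- which.max(candY)
      Y[i, j] <- candY[kY]; ptrY[i, j] <- c(1L, 3L)[kY]
    }
  }
  st <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  ident <- 0L; aligned <- 0L
  while (i > 1 || j > 1) {
    if (st == 1L) {
      aligned <- aligned + 1L
      if (av[i - 1] == bv[j - 1]) ident <- ident + 1L
      st <- ptrM[i, j]; i <- i - 1; j <- j - 1
    } else if (st == 2L) {
      st <- ptrX[i, j]; i <- i - 1
    } else {
      st <- ptrY[i, j]; j <- j - 1
    }
  }
  if (aligned == 0L) return(0)
  structure(ident / aligned,
            score = max(c(M[n + 1, m + 1], X[n + 1, m + 1],
                          Y[n + 1, m + 1])))
}

# exact one-sided (greater) Fisher p by explicit hypergeometric enumeration
hyper_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(m, k)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  sum(probs[xs >= a])
}

# exhaustive duplication-loss cost oracle: minimum cost over all mappings
# of internal gene nodes to species nodes consistent with the leaves
recon_cost_oracle <- function(gene_tree, species_tree, prefix_map) {
  gp <- chemrep:::phylo_parents(gene_tree)
  gk <- chemrep:::phylo_children(gene_tree)
  sp <- chemrep:::phylo_parents(species_tree)
  sd <- chemrep:::phylo_depths(species_tree, sp)
  ng <- length(gp); ns <- length(sp)
  anc_or_eq <- function(a, v) {
    while (!is.na(v) && sd[v] > sd[a]) v <- sp[v]
    !is.na(v) && v == a
  }
  slca <- function(a, b) {
    while (a != b) if (sd[a] >= sd[b]) a <- sp[a] else b <- sp[b]
    a
  }
  leafmap <- match(
    chemrep::species_of_leaf(gene_tree$tip.label, prefix_map),
    species_tree$tip.label)
  internal <- which(lengths(gk) > 0)
  assign_cost <- function(Mfull) {
    dups <- 0L; loss <- 0L
    isdup <- logical(ng)
    for (v in internal) {
      ch <- gk[[v]]
      l <- slca(Mfull[ch[1]], Mfull[ch[2]])
      if (!anc_or_eq(Mfull[v], l)) return(Inf)
      isdup[v] <- Mfull[v] == Mfull[ch[1]] || Mfull[v] == Mfull[ch[2]] ||
        Mfull[v] != l
      if (isdup[v]) dups <- dups + 1L
    }
    for (v in seq_len(ng)) {
      u <- gp[v]
      if (is.na(u)) next
      if (!anc_or_eq(Mfull[u], Mfull[v])) return(Inf)
      k <- sd[Mfull[v]] - sd[Mfull[u]]
      loss <- loss + max(0L, k - 1L + as.integer(isdup[u]))
    }
    dups + loss
  }
  Mfull <- rep(NA_integer_, ng)
  Mfull[seq_along(leafmap)] <- leafmap
  best <- Inf
  rec <- function(idx) {
    if (idx > length(internal)) {
      best <<- min(best, assign_cost(Mfull))
      return(invisible())
    }
    v <- internal[idx]
    for (s in seq_len(ns)) {
      Mfull[v] <<- s
      rec(idx + 1L)
    }
    Mfull[v] <<- NA_integer_
  }
  rec(1L)
  best
}

# all rooted binary topologies on a given set of labelled leaves, as newick
all_rooted_topologies <- function(labels) {
  if (length(labels) == 1L) return(labels)
  out <- character(0)
  n <- length(labels)
  # split the first label off with every subset of the rest
  rest <- labels[-1]
  subsets <- unlist(lapply(0:(length(rest) - 1), function(k)
    utils::combn(rest, k, simplify = FALSE)), recursive = FALSE)
  for (s in subsets) {
    left <- c(labels[1], s)
    right <- setdiff(labels, left)
    if (!length(right)) next
    for (lt in all_rooted_topologies(left))
      for (rt in all_rooted_topologies(right))
        out <- c(out, paste0("(", lt, ",", rt, ")"))
  }
  out
}

# direct state-summation codon log-likelihood (no pruning): sums over all
# joint internal-node states using R-built transition matrices
brute_force_codon_loglik <- function(aln, tree, kappa, omega, pi) {
  u <- chemrep::sense_codons()
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  rc <- chemrep:::rate_coefs(pi)
  cscale <- (rc[1] + kappa * rc[2]) + omega * (rc[3] + kappa * rc[4])
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    chemrep:::gy94_transition_probs(kappa, omega, pi,
                                    tree$edge.length[e] / cscale,
                                    scale = FALSE))
  internals <- setdiff(seq_len(nnode), seq_len(ntip))
  tipstate <- matrix(match(aln[tree$tip.label, , drop = FALSE], u),
                     ntip, ncol(aln))
  grid <- as.matrix(do.call(expand.grid,
                            rep(list(seq_along(u)), length(internals))))
  colnames(grid) <- NULL
  pos <- function(node) match(node, internals)
  total <- 0
  for (site in seq_len(ncol(aln))) {
    pr <- pi[grid[, pos(root)]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      par_states <- grid[, pos(par)]
      if (ch <= ntip) {
        s <- tipstate[ch, site]
        if (is.na(s)) next  # gap tip: marginal sum over states is 1
        ch_states <- rep(s, nrow(grid))
      } else {
        ch_states <- grid[, pos(ch)]
      }
      pr <- pr * P[[e]][cbind(par_states, ch_states)]
    }
    total <- total + log(sum(pr))
  }
  unname(total)
}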