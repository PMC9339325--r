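# Goldman-Yang (GY94) codon substitution machinery over the 61 sense codons
# of the standard genetic code: rate matrix construction, F3x4 equilibrium
# frequencies, transition probabilities, and forward simulation.

codon_universe <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    nt <- c("T", "C", "A", "G")
    codons <- as.vector(t(outer(
      as.vector(t(outer(nt, nt, paste0))), nt, paste0)))
    gc <- Biostrings::GENETIC_CODE
    aa <- unname(gc[codons])
    sense <- codons[aa != "*"]
    aa <- aa[match(sense, codons)]
    n <- length(sense)  # 61
    cm <- do.call(rbind, strsplit(sense, ""))
    # pair type for single-nucleotide changes:
    # 0 none/multiple, 1 syn transversion, 2 syn transition,
    # 3 nonsyn transversion, 4 nonsyn transition
    type <- matrix(0L, n, n)
    is_ts <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        diffs <- which(cm[i, ] != cm[j, ])
        if (length(diffs) != 1L) next
        ts <- is_ts(cm[i, diffs], cm[j, diffs])
        ns <- aa[i] != aa[j]
        type[i, j] <- type[j, i] <- 1L + ts + 2L * ns
      }
    }
    cache <<- list(codons = sense, aa = aa, base = cm, type = type)
    cache
  }
})

#' The 61 sense codons of the standard genetic code
#' @return character vector of codons (TCAG order within positions).
#' @export
sense_codons <- function() codon_universe()$codons

#' Amino acids encoded by [sense_codons()]
#' @return character vector of one-letter amino acids along [sense_codons()].
#' @export
sense_codon_aa <- function() codon_universe()$aa

#' F3x4 codon equilibrium frequencies
#'
#' Position-specific nucleotide frequencies are estimated from the codon
#' columns of an alignment (gaps ignored) and multiplied per codon, then
#' renormalized over the 61 sense codons. A small pseudocount keeps every
#' frequency strictly positive.
#'
#' @param alignment codon alignment: character matrix of codon strings
#'   (rows = taxa), `"---"` for gaps.
#' @param pseudocount added per nucleotide per position (default 0.5).
#' @return numeric vector of length 61, summing to 1, named by codon.
#' @export
f3x4_freqs <- function(alignment, pseudocount = 0.5) {
  stopifnot(is.matrix(alignment))
  nt <- c("T", "C", "A", "G")
  cod <- alignment[alignment != "---" & !is.na(alignment)]
  if (!length(cod)) stop("alignment has no ungapped codons")
  mat <- do.call(rbind, strsplit(cod, ""))
  posfreq <- sapply(1:3, function(k) {
    cnt <- table(factor(mat[, k], levels = nt)) + pseudocount
    as.numeric(cnt / sum(cnt))
  })
  rownames(posfreq) <- nt
  u <- codon_universe()
  pi <- posfreq[u$base[, 1], 1] * posfreq[u$base[, 2], 2] *
    posfreq[u$base[, 3], 3]
  pi <- pi / sum(pi)
  stats::setNames(pi, u$codons)
}

#' Uniform codon frequencies
#' @return vector of 1/61 per sense codon.
#' @export
uniform_codon_freqs <- function() {
  u <- codon_universe()
  stats::setNames(rep(1 / length(u$codons), length(u$codons)), u$codons)
}

#' GY94 codon rate matrix
#'
#' Instantaneous rates between sense codons differing at a single
#' nucleotide: `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]`,
#' zero for multi-nucleotide changes, diagonal set so rows sum to zero. By
#' default the matrix is rescaled so the expected number of substitutions
#' per codon site per unit time at equilibrium is 1.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi codon equilibrium frequencies over [sense_codons()].
#' @param scale rescale to unit expected rate (default TRUE).
#' @return 61x61 generator matrix, dimnames = codons.
#' @export
gy94_rate_matrix <- function(kappa, omega, pi = uniform_codon_freqs(),
                             scale = TRUE) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61, all(pi > 0))
  u <- codon_universe()
  mult <- c(0, 1, kappa, omega, kappa * omega)[u$type + 1L]
  Q <- matrix(mult, 61, 61) * rep(pi, each = 61)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  if (scale) {
    rate <- -sum(pi * diag(Q))
    if (rate > 0) Q <- Q / rate
  }
  dimnames(Q) <- list(u$codons, u$codons)
  Q
}

# expected substitution rate of the *unscaled* GY94 process
gy94_rate <- function(kappa, omega, pi) {
  u <- codon_universe()
  mult <- c(0, 1, kappa, omega, kappa * omega)[u$type + 1L]
  Q <- matrix(mult, 61, 61) * rep(pi, each = 61)
  sum(pi * rowSums(Q))
}

# transition probability matrix P(t) = exp(Qt) via symmetric eigen
# decomposition (the GY94 chain is reversible w.r.t. pi)
gy94_transition_probs <- function(kappa, omega, pi, t, scale = TRUE) {
  Q <- gy94_rate_matrix(kappa, omega, pi, scale = scale)
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  P <- (1 / d) * (eig$vectors %*%
    (exp(eig$values * t) * t(eig$vectors))) * rep(d, each = 61)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

# -- site-class mixtures ------------------------------------------------------

#' Discretized site-class specification for the supported codon models
#'
#' M0 is a single class at `omega`. M8 puts weight `p0` on a beta(p, q)
#' distribution over omega in (0, 1), discretized into `ncat` equal-
#' probability classes at quantile midpoints, plus weight `1 - p0` on
#' `omega_s >= 1`; M8a is M8 with `omega_s` fixed at 1. The branch-site
#' model A has four classes with distinct background/foreground omegas.
#'
#' @param model `"M0"`, `"M8"`, `"M8a"` or `"bsA"`.
#' @param omega M0 omega.
#' @param p0,p_beta,q_beta,omega_s M8/M8a parameters.
#' @param bs_p0,bs_p1,omega0,omega2 branch-site model A parameters.
#' @param ncat number of beta discretization classes (default 10).
#' @return data.frame with columns `prob`, `omega_bg`, `omega_fg`.
#' @export
site_classes <- function(model, omega = NULL, p0 = NULL, p_beta = NULL,
                         q_beta = NULL, omega_s = NULL, bs_p0 = NULL,
                         bs_p1 = NULL, omega0 = NULL, omega2 = NULL,
                         ncat = 10L) {
  model <- match.arg(model, c("M0", "M8", "M8a", "bsA"))
  if (model == "M0") {
    return(data.frame(prob = 1, omega_bg = omega, omega_fg = omega))
  }
  if (model %in% c("M8", "M8a")) {
    if (model == "M8a") omega_s <- 1
    stopifnot(p0 >= 0, p0 <= 1, p_beta > 0, q_beta > 0, omega_s >= 1)
    qs <- stats::qbeta((2 * seq_len(ncat) - 1) / (2 * ncat), p_beta, q_beta)
    qs <- pmin(pmax(qs, 1e-8), 1 - 1e-8)
    return(data.frame(prob = c(rep(p0 / ncat, ncat), 1 - p0),
                      omega_bg = c(qs, omega_s),
                      omega_fg = c(qs, omega_s)))
  }
  # branch-site model A
  stopifnot(bs_p0 >= 0, bs_p1 >= 0, bs_p0 + bs_p1 <= 1,
            omega0 >= 0, omega0 <= 1, omega2 >= 1)
  p2 <- 1 - bs_p0 - bs_p1
  w0 <- if (bs_p0 + bs_p1 > 0) bs_p0 / (bs_p0 + bs_p1) else 0.5
  data.frame(prob = c(bs_p0, bs_p1, p2 * w0, p2 * (1 - w0)),
             omega_bg = c(omega0, 1, omega0, 1),
             omega_fg = c(omega0, 1, omega2, omega2))
}

# -- forward simulation -------------------------------------------------------

#' Simulate a codon alignment along a tree under a GY94 regime
#'
#' Sites are assigned to the model's discretized omega classes; for each
#' class exact transition probabilities `exp(Qt)` are computed per branch
#' and states are propagated from a root draw at equilibrium. Branch
#' lengths are interpreted as expected substitutions per codon site under
#' the class mixture. For the branch-site regime, `foreground_edge` selects
#' the tree edge that uses the foreground omegas.
#'
#' @param tree rooted `ape::phylo` with branch lengths.
#' @param params list with `kappa`, optional `pi`, and the [site_classes()]
#'   model fields (`model = "M0"`, `"M8"`, `"M8a"` or `"bsA"` plus its
#'   parameters).
#' @param n_codons number of codon sites.
#' @param seed RNG seed (mandatory: generators are seed-deterministic).
#' @param foreground_edge edge index (row of `tree$edge`) for `"bsA"`.
#' @return codon alignment matrix (taxa x sites) with attributes
#'   `"site_class"` (1-based class index per site), `"site_omega"`
#'   (background omega per site), `"classes"` (the class table) and
#'   `"node_states"` (codon state matrix for all tree nodes, for ancestral
#'   bookkeeping).
#' @export
simulate_codon_alignment <- function(tree, params, n_codons, seed,
                                     foreground_edge = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  stopifnot(!is.null(tree$edge.length))
  kappa <- params$kappa
  pi <- if (!is.null(params$pi)) params$pi else uniform_codon_freqs()
  cls <- do.call(site_classes, params[setdiff(names(params),
                                              c("kappa", "pi"))])
  if (identical(params$model, "bsA") && is.null(foreground_edge))
    stop("foreground_edge is required for the branch-site regime")
  ncls <- nrow(cls)
  # common scaling: unit expected rate under the background class mixture
  rates <- vapply(cls$omega_bg, function(w) gy94_rate(kappa, w, pi),
                  numeric(1))
  cscale <- sum(cls$prob * rates)
  u <- codon_universe()
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # per class x edge transition matrices
  Plist <- vector("list", ncls)
  for (k in seq_len(ncls)) {
    Plist[[k]] <- lapply(seq_len(nrow(tree$edge)), function(e) {
      w <- if (!is.null(foreground_edge) && e %in% foreground_edge)
        cls$omega_fg[k] else cls$omega_bg[k]
      gy94_transition_probs(kappa, w, pi, tree$edge.length[e] / cscale,
                            scale = FALSE)
    })
  }
  site_class <- sample.int(ncls, n_codons, replace = TRUE, prob = cls$prob)
  states <- matrix(NA_integer_, nnode, n_codons)
  states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
  # edges ordered parent-before-child
  depth <- phylo_depths(tree)
  eord <- order(depth[tree$edge[, 2]])
  for (e in eord) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    for (k in unique(site_class)) {
      idx <- which(site_class == k)
      P <- Plist[[k]][[e]]
      ps <- states[par, idx]
      for (s in unique(ps)) {
        ii <- idx[ps == s]
        states[child, ii] <- sample.int(61, length(ii), replace = TRUE,
                                        prob = P[s, ])
      }
    }
  }
  aln <- matrix(u$codons[states[seq_len(ntip), , drop = FALSE]],
                ntip, n_codons)
  rownames(aln) <- tree$tip.label
  structure(aln,
            site_class = site_class,
            site_omega = cls$omega_bg[site_class],
            classes = cls,
            node_states = states)
}
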