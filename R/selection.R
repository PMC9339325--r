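# The gated dN/dS selection screen: codon-alignment preparation, maximum-
# likelihood fits of M0 / M8 / M8a / branch-site model A, likelihood-ratio
# tests, and the omega-gated cascade with per-branch q-values.

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned amino-acid column becomes a codon column of the matching
#' CDS; gap columns become codon gaps (`"---"`). The ungapped protein must
#' equal the translation of its CDS (terminal stop codons are tolerated and
#' trimmed); internal stops are an error, since pseudogenes are excluded
#' from selection analyses.
#'
#' @param protein_alignment named character vector of equal-length aligned
#'   protein sequences (`-` for gaps).
#' @param cds_map named character vector of unaligned CDS nucleotide
#'   sequences covering the same names.
#' @return codon alignment matrix (taxa x codon columns).
#' @export
backtranslate_alignment <- function(protein_alignment, cds_map) {
  ids <- names(protein_alignment)
  if (is.null(ids)) stop("protein alignment must be named")
  if (length(unique(nchar(protein_alignment))) != 1L)
    stop("aligned proteins must have equal length")
  miss <- setdiff(ids, names(cds_map))
  if (length(miss)) stop("no CDS for: ", paste(miss, collapse = ", "))
  width <- nchar(protein_alignment[[1]])
  out <- matrix("---", length(ids), width, dimnames = list(ids, NULL))
  for (id in ids) {
    aa <- strsplit(protein_alignment[[id]], "")[[1]]
    cds <- cds_map[[id]]
    prot <- translate_cds(cds)
    if (endsWith(prot, "*")) {
      prot <- substr(prot, 1, nchar(prot) - 1L)
      cds <- substr(cds, 1, 3L * nchar(prot))
    }
    if (grepl("\\*", prot))
      stop("internal stop codon in CDS of '", id,
           "' (pseudogenes are excluded from codon alignments)")
    ungapped <- paste(aa[aa != "-"], collapse = "")
    if (!identical(ungapped, prot))
      stop("protein of '", id, "' does not match the translation of its CDS")
    if (nchar(cds) != 3L * nchar(prot))
      stop("CDS length of '", id, "' is not 3x its protein length")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    out[id, aa != "-"] <- codons
  }
  out
}

#' Drop sequences that introduce large gaps in a codon alignment
#'
#' Rows whose gap fraction exceeds `max_gap_fraction` are removed, then
#' columns left with gaps in every remaining row are removed (they carry no
#' signal). Removing a gappy row can only reduce the surviving rows' gap
#' fractions once all-gap columns are pruned.
#'
#' @param alignment codon alignment matrix.
#' @param max_gap_fraction maximum tolerated per-row gap fraction
#'   (default 0.5).
#' @return filtered codon alignment matrix.
#' @export
drop_gappy_sequences <- function(alignment, max_gap_fraction = 0.5) {
  stopifnot(is.matrix(alignment))
  gapfrac <- rowMeans(alignment == "---")
  keep <- gapfrac <= max_gap_fraction
  if (!any(keep)) stop("all sequences exceed the gap-fraction threshold")
  out <- alignment[keep, , drop = FALSE]
  allgap <- colSums(out != "---") == 0L
  out[, !allgap, drop = FALSE]
}

#' Split aligned CDS strings into a codon alignment matrix
#'
#' @param nuc named character vector of aligned nucleotide sequences whose
#'   lengths are divisible by 3 (`-` gaps in codon-sized runs).
#' @return codon alignment matrix.
#' @export
codon_alignment_from_nuc <- function(nuc) {
  if (is.null(names(nuc))) stop("sequences must be named")
  w <- unique(nchar(nuc))
  if (length(w) != 1L || w %% 3L != 0L)
    stop("aligned sequences must share a length divisible by 3")
  t(vapply(nuc, function(s)
    substring(s, seq(1, w, 3), seq(3, w, 3)), character(w / 3)))
}

# -- likelihood machinery -----------------------------------------------------

# compress a codon alignment into integer tip patterns for the C++ pruning
# kernel; validates against stop codons
codon_data <- function(alignment) {
  stopifnot(is.matrix(alignment), !is.null(rownames(alignment)))
  u <- codon_universe()
  idx <- match(alignment, u$codons)           # NA for gaps/unknown
  stopmask <- is.na(idx) & alignment != "---" &
    !grepl("[^ACGT]", alignment)
  if (any(stopmask))
    stop("stop codon(s) in codon alignment at column(s) ",
         paste(unique(ceiling(which(stopmask) / nrow(alignment))),
               collapse = ", "))
  code <- matrix(ifelse(is.na(idx), -1L, idx - 1L), nrow(alignment))
  key <- apply(code, 2, paste, collapse = ",")
  upat <- !duplicated(key)
  pattern_of_site <- match(key, key[upat])
  tipdata <- code[, upat, drop = FALSE]
  list(tipdata = tipdata, weights = as.numeric(table(pattern_of_site)),
       pattern_of_site = pattern_of_site, taxa = rownames(alignment),
       nsite = ncol(alignment))
}

# edges of a rooted tree ordered children-before-parent, tips matched to
# alignment rows
tree_data <- function(tree, taxa) {
  m <- match(tree$tip.label, taxa)
  if (anyNA(m))
    stop("tree tips absent from alignment: ",
         paste(tree$tip.label[is.na(m)], collapse = ", "))
  if (length(taxa) != length(tree$tip.label))
    stop("alignment rows absent from tree")
  depth <- phylo_depths(tree)
  eord <- order(depth[tree$edge[, 2]], decreasing = TRUE)
  list(edge = tree$edge[eord, , drop = FALSE], eord = eord,
       tip_perm = m, nnode = ape::Ntip(tree) + tree$Nnode)
}

# pair-count decomposition of the GY94 expected rate: for fixed pi the
# unscaled rate is (S_tv + kappa*S_ts) + omega*(N_tv + kappa*N_ts)
rate_coefs <- function(pi) {
  u <- codon_universe()
  pp <- pi %o% pi
  vapply(1:4, function(k) sum(pp[u$type == k]), numeric(1))
}

# mixture log-likelihood; returns total lnL plus per-pattern per-class
# log-likelihood matrix (for empirical-Bayes site posteriors)
mixture_loglik <- function(cd, td, blen, kappa, pi, classes,
                           foreground_edge = NULL, details = FALSE,
                           rc = rate_coefs(pi)) {
  rates <- (rc[1] + kappa * rc[2]) + classes$omega_bg * (rc[3] + kappa * rc[4])
  cscale <- sum(classes$prob * rates)
  blen_eff <- pmax(blen[td$eord], 1e-9) / cscale
  nedge <- nrow(td$edge)
  ncls <- nrow(classes)
  omega_mat <- matrix(classes$omega_bg, nedge, ncls, byrow = TRUE)
  if (!is.null(foreground_edge)) {
    fg_rows <- match(foreground_edge, td$eord)
    omega_mat[fg_rows, ] <- rep(classes$omega_fg, each = length(fg_rows))
  }
  ll <- t(cr_site_loglik_classes(cd$tipdata[td$tip_perm, , drop = FALSE],
                                 td$edge, blen_eff,
                                 omega_mat, kappa, unname(pi),
                                 codon_universe()$type, td$nnode))
  mx <- apply(ll, 2, max)
  site_l <- colSums(classes$prob * exp(sweep(ll, 2, mx)))
  total <- sum(cd$weights * (log(site_l) + mx))
  if (!details) return(total)
  list(lnL = total, class_loglik = ll)
}

#' Log-likelihood of a codon alignment under a GY94 site-class model
#'
#' Felsenstein pruning over the 61 sense codons; gaps are treated as
#' missing data; site classes are mixed at each site with their class
#' probabilities. Branch lengths are taken from `tree$edge.length` and are
#' interpreted as expected substitutions per codon site under the class
#' mixture.
#'
#' @param alignment codon alignment matrix (taxa x codon columns).
#' @param tree rooted `ape::phylo` with branch lengths; tips must match the
#'   alignment rows.
#' @param params list with `kappa`, optional `pi` (default F3x4 from the
#'   alignment), and either `omega` (single-class M0) or a [site_classes()]
#'   table as `classes`; `foreground_edge` selects foreground edges for
#'   branch-site class tables.
#' @return total log-likelihood (numeric scalar).
#' @export
codon_log_likelihood <- function(alignment, tree, params) {
  cd <- codon_data(alignment)
  td <- tree_data(tree, cd$taxa)
  pi <- if (!is.null(params$pi)) params$pi else f3x4_freqs(alignment)
  classes <- if (!is.null(params$classes)) params$classes
             else site_classes("M0", omega = params$omega)
  mixture_loglik(cd, td, tree$edge.length, params$kappa, pi, classes,
                 foreground_edge = params$foreground_edge)
}

# -- optimization helpers -----------------------------------------------------

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

fit_with_restarts <- function(obj, start, lower = -Inf, upper = Inf,
                              restarts = 0L, jitter_sd = 0.3, seed = 7L,
                              control = list(rel.tol = 1e-8, iter.max = 400,
                                             eval.max = 1200)) {
  best <- stats::nlminb(start, obj, lower = lower, upper = upper,
                        control = control)
  if (restarts > 0L) {
    jit <- withr_seed_matrix(seed, restarts, length(start), jitter_sd)
    for (r in seq_len(restarts)) {
      cand <- try(stats::nlminb(start + jit[r, ], obj, lower = lower,
                                upper = upper, control = control),
                  silent = TRUE)
      if (!inherits(cand, "try-error") &&
          is.finite(cand$objective) && cand$objective < best$objective)
        best <- cand
    }
  }
  best
}

# deterministic jitter matrix without touching the global RNG stream
withr_seed_matrix <- function(seed, n, k, sd) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(stats::rnorm(n * k, 0, sd), n, k)
}

new_codon_fit <- function(model, lnL, kappa, pi, tree, extra = list(),
                          npar, convergence) {
  structure(c(list(model = model, lnL = lnL, kappa = kappa, pi = pi,
                   tree = tree, npar = npar, convergence = convergence),
              extra),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("GY94 %s fit: lnL = %.4f (np = %d)\n", x$model, x$lnL, x$npar))
  cat(sprintf("  kappa = %.4f", x$kappa))
  if (!is.null(x$omega)) cat(sprintf("  omega = %.5f", x$omega))
  cat("\n")
  if (!is.null(x$p0))
    cat(sprintf("  p0 = %.3f  beta(p = %.3f, q = %.3f)  omega_s = %.3f\n",
                x$p0, x$p_beta, x$q_beta, x$omega_s))
  invisible(x)
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$lnL, df = object$npar, class = "logLik")
}

#' @export
coef.codon_fit <- function(object, ...) {
  out <- c(kappa = object$kappa)
  for (nm in c("omega", "p0", "p_beta", "q_beta", "omega_s",
               "omega0", "omega2", "p1"))
    if (!is.null(object[[nm]])) out[nm] <- object[[nm]]
  out
}

#' Fit the M0 (single global omega) codon model
#'
#' Box-constrained maximum likelihood over kappa, omega and all branch
#' lengths (quasi-Newton on log-transformed rates). An invariant alignment
#' (all rows identical) makes omega unidentifiable and raises a diagnostic
#' error.
#'
#' @param alignment codon alignment matrix.
#' @param tree rooted binary `ape::phylo`; starting branch lengths taken
#'   from the tree when present.
#' @param pi codon frequencies (default F3x4 estimated from the alignment).
#' @param kappa_init,omega_init optimizer starting values.
#' @param restarts number of deterministic jittered restarts.
#' @return `codon_fit` object with `omega`, `kappa`, fitted `tree` (branch
#'   lengths in expected substitutions per codon site), `lnL`.
#' @export
fit_m0 <- function(alignment, tree, pi = NULL, kappa_init = 2,
                   omega_init = 0.3, restarts = 0L) {
  cd <- codon_data(alignment)
  if (ncol(cd$tipdata) == 1L ||
      all(apply(cd$tipdata, 2, function(z) length(unique(z[z >= 0]))) <= 1L))
    stop("alignment is invariant across sequences: ",
         "omega is unidentifiable (no substitutions observed)")
  td <- tree_data(tree, cd$taxa)
  if (is.null(pi)) pi <- f3x4_freqs(alignment)
  nedge <- nrow(tree$edge)
  bl0 <- if (!is.null(tree$edge.length)) pmax(tree$edge.length, 1e-3)
         else rep(0.1, nedge)
  start <- c(log(kappa_init), log(omega_init), log(bl0))
  obj <- function(par) {
    kappa <- exp(par[1]); omega <- exp(par[2]); bl <- exp(par[3:length(par)])
    cls <- site_classes("M0", omega = omega)
    -mixture_loglik(cd, td, bl, kappa, pi, cls)
  }
  lower <- c(log(1e-3), log(1e-6), rep(log(1e-7), nedge))
  upper <- c(log(100), log(20), rep(log(30), nedge))
  opt <- fit_with_restarts(obj, start, lower, upper, restarts = restarts)
  fitted_tree <- tree
  fitted_tree$edge.length <- exp(opt$par[3:length(opt$par)])
  new_codon_fit("M0", -opt$objective, exp(opt$par[1]), pi, fitted_tree,
                extra = list(omega = exp(opt$par[2])),
                npar = length(opt$par), convergence = opt$convergence)
}

# shared machinery for the site-mixture fits: optimizes a branch-length
# scale on top of the M0 tree plus the mixture parameters
fit_mixture_model <- function(cd, td, pi, base_blen, kappa_init, make_classes,
                              start_theta, lower_theta, upper_theta,
                              foreground_edge = NULL, restarts = 0L) {
  obj <- function(par) {
    s <- exp(par[1]); kappa <- exp(par[2])
    cls <- make_classes(par[-(1:2)])
    -mixture_loglik(cd, td, base_blen * s, kappa, pi, cls,
                    foreground_edge = foreground_edge)
  }
  start <- c(0, log(kappa_init), start_theta)
  lower <- c(log(1e-3), log(1e-3), lower_theta)
  upper <- c(log(1e3), log(100), upper_theta)
  opt <- fit_with_restarts(obj, start, lower, upper, restarts = restarts)
  list(opt = opt, scale = exp(opt$par[1]), kappa = exp(opt$par[2]),
       theta = opt$par[-(1:2)], lnL = -opt$objective)
}

#' M8 vs M8a likelihood-ratio test for positive selection on sites
#'
#' Fits M0 first (branch lengths, kappa), then M8a (beta-distributed omega
#' plus a class fixed at omega = 1) and M8 (the extra class free,
#' omega_s >= 1), re-optimizing a common branch-length scale, kappa and the
#' mixture parameters under each model; M8 is warm-started from the M8a
#' optimum, which also enforces the nesting lnL(M8) >= lnL(M8a). The LRT
#' compares 2*(lnL_M8 - lnL_M8a), clamped at 0, to chi-square(df = 1) --
#' conservative for this boundary hypothesis.
#'
#' @inheritParams fit_m0
#' @param m0 optional precomputed [fit_m0()] result.
#' @param ncat beta discretization classes (default 10).
#' @return object of class `m8_test`: `lnL_m8`, `lnL_m8a`, `p_value`, the
#'   two fits and the M0 fit.
#' @export
fit_m8_pair <- function(alignment, tree, pi = NULL, m0 = NULL, ncat = 10L,
                        restarts = 0L) {
  cd <- codon_data(alignment)
  td <- tree_data(tree, cd$taxa)
  if (is.null(m0)) m0 <- fit_m0(alignment, tree, pi = pi)
  pi <- m0$pi
  base_blen <- m0$tree$edge.length
  # theta = (logit p0, log p_beta, log q_beta [, log(omega_s - 1)])
  mk_m8a <- function(th) site_classes("M8a", p0 = inv_logit(th[1]),
                                      p_beta = exp(th[2]),
                                      q_beta = exp(th[3]), ncat = ncat)
  mk_m8 <- function(th) site_classes("M8", p0 = inv_logit(th[1]),
                                     p_beta = exp(th[2]),
                                     q_beta = exp(th[3]),
                                     omega_s = 1 + exp(th[4]), ncat = ncat)
  th_lower <- c(logit(1e-4), log(0.05), log(0.05))
  th_upper <- c(logit(1 - 1e-4), log(50), log(50))
  f_m8a <- fit_mixture_model(cd, td, pi, base_blen, m0$kappa, mk_m8a,
                             start_theta = c(logit(0.85), log(0.5), log(1.5)),
                             lower_theta = th_lower, upper_theta = th_upper,
                             restarts = restarts)
  f_m8 <- fit_mixture_model(cd, td, pi, base_blen, f_m8a$kappa, mk_m8,
                            start_theta = c(f_m8a$theta, log(0.2)),
                            lower_theta = c(th_lower, log(1e-6)),
                            upper_theta = c(th_upper, log(30)),
                            restarts = restarts)
  lnL_m8 <- max(f_m8$lnL, f_m8a$lnL)   # nesting: M8a is M8 at omega_s = 1
  stat <- max(0, 2 * (lnL_m8 - f_m8a$lnL))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  mk_fit <- function(f, model, mk, extra_names) {
    cls_par <- list(p0 = inv_logit(f$theta[1]), p_beta = exp(f$theta[2]),
                    q_beta = exp(f$theta[3]))
    if (model == "M8") cls_par$omega_s <- 1 + exp(f$theta[4])
    else cls_par$omega_s <- 1
    ft <- tree; ft$edge.length <- base_blen * f$scale
    new_codon_fit(model, f$lnL, f$kappa, pi, ft, extra = cls_par,
                  npar = length(f$opt$par) + length(base_blen),
                  convergence = f$opt$convergence)
  }
  structure(list(lnL_m8 = lnL_m8, lnL_m8a = f_m8a$lnL, statistic = stat,
                 p_value = p, m8 = mk_fit(f_m8, "M8"),
                 m8a = mk_fit(f_m8a, "M8a"), m0 = m0),
            class = "m8_test")
}

#' @export
print.m8_test <- function(x, ...) {
  cat(sprintf("M8 vs M8a LRT: lnL_M8 = %.4f, lnL_M8a = %.4f, 2dlnL = %.4f, p = %.5g\n",
              x$lnL_m8, x$lnL_m8a, x$statistic, x$p_value))
  invisible(x)
}

#' Branch-site model A test on a foreground branch
#'
#' The alternative model allows a site class with omega_2 >= 1 on the
#' foreground branch (model A); the null fixes omega_2 = 1. Both share the
#' M0 branch lengths up to a re-optimized scale. p-values come from
#' chi-square(df = 1) on the clamped LRT statistic. Sites assigned to the
#' positively selected classes with naive empirical-Bayes posterior above
#' `site_posterior` are reported.
#'
#' @inheritParams fit_m8_pair
#' @param foreground_edge row index of `tree$edge` designating the
#'   foreground branch.
#' @param site_posterior posterior threshold for site identification.
#' @return object of class `branch_site_test` with `lnL_alt`, `lnL_null`,
#'   `p_value`, `selected_sites` (1-based alignment columns) and
#'   `posterior` per site.
#' @export
fit_branch_site <- function(alignment, tree, foreground_edge, pi = NULL,
                            m0 = NULL, site_posterior = 0.95,
                            restarts = 0L) {
  cd <- codon_data(alignment)
  td <- tree_data(tree, cd$taxa)
  if (is.null(m0)) m0 <- fit_m0(alignment, tree, pi = pi)
  pi <- m0$pi
  base_blen <- m0$tree$edge.length
  # theta = (a, b [, log(omega2 - 1)]): p0 = e^a/(1+e^a+e^b), p1 likewise,
  # omega0 via logit
  props <- function(a, b) {
    z <- 1 + exp(a) + exp(b)
    c(p0 = exp(a) / z, p1 = exp(b) / z)
  }
  mk_null <- function(th) {
    pr <- props(th[1], th[2])
    site_classes("bsA", bs_p0 = pr[1], bs_p1 = pr[2],
                 omega0 = inv_logit(th[3]), omega2 = 1)
  }
  mk_alt <- function(th) {
    pr <- props(th[1], th[2])
    site_classes("bsA", bs_p0 = pr[1], bs_p1 = pr[2],
                 omega0 = inv_logit(th[3]), omega2 = 1 + exp(th[4]))
  }
  th_l <- c(-12, -12, logit(1e-5)); th_u <- c(12, 12, logit(1 - 1e-5))
  w0_init <- logit(min(max(m0$omega, 1e-4), 1 - 1e-4))
  f_null <- fit_mixture_model(cd, td, pi, base_blen, m0$kappa, mk_null,
                              start_theta = c(1.5, 0, w0_init),
                              lower_theta = th_l, upper_theta = th_u,
                              foreground_edge = foreground_edge)
  f_alt <- fit_mixture_model(cd, td, pi, base_blen, f_null$kappa, mk_alt,
                             start_theta = c(f_null$theta, log(0.5)),
                             lower_theta = c(th_l, log(1e-6)),
                             upper_theta = c(th_u, log(30)),
                             foreground_edge = foreground_edge)
  lnL_alt <- max(f_alt$lnL, f_null$lnL)
  stat <- max(0, 2 * (lnL_alt - f_null$lnL))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  # empirical-Bayes site posteriors for the omega2 classes under the alt fit
  cls <- mk_alt(f_alt$theta)
  det <- mixture_loglik(cd, td, base_blen * f_alt$scale, f_alt$kappa, pi,
                        cls, foreground_edge = foreground_edge,
                        details = TRUE)
  ll <- det$class_loglik
  mx <- apply(ll, 2, max)
  post <- cls$prob * exp(sweep(ll, 2, mx))
  post <- sweep(post, 2, colSums(post), "/")
  sel_pat <- colSums(post[3:4, , drop = FALSE])
  site_post <- sel_pat[cd$pattern_of_site]
  structure(list(lnL_alt = lnL_alt, lnL_null = f_null$lnL, statistic = stat,
                 p_value = p,
                 foreground_edge = foreground_edge,
                 posterior = site_post,
                 selected_sites = which(site_post > site_posterior),
                 omega2 = 1 + exp(f_alt$theta[4]),
                 kappa = f_alt$kappa),
            class = "branch_site_test")
}

#' @export
print.branch_site_test <- function(x, ...) {
  cat(sprintf("Branch-site model A (edge %s): 2dlnL = %.4f, p = %.5g, omega2 = %.3f\n",
              paste(x$foreground_edge, collapse = ","), x$statistic,
              x$p_value, x$omega2))
  if (length(x$selected_sites))
    cat("  selected sites:", paste(x$selected_sites, collapse = ", "), "\n")
  invisible(x)
}

#' Run the gated selection-screen cascade over clades
#'
#' For each clade: fit M0 and record the global omega. Only when omega
#' exceeds `omega_gate` (0.3 by default) is the M8-vs-M8a site test run;
#' only when that test is significant at `alpha` are branch-site tests run
#' on every terminal branch, with q-value correction across the branches of
#' the clade (BH for < 100 tests, Storey's estimator otherwise). Branches
#' with q below `q_threshold` are reported as positively selected along
#' with their high-posterior sites. Every skipped stage records the gate
#' value that caused the skip.
#'
#' @param clade_alignments named list of codon alignment matrices.
#' @param clade_trees named list of rooted trees (same names).
#' @param omega_gate M0 omega threshold gating the site test.
#' @param alpha significance level for the M8-vs-M8a LRT.
#' @param q_threshold q-value threshold for branch-level selection calls.
#' @param site_posterior posterior threshold for site identification.
#' @return object of class `cascade_report`: `summary` data.frame (one row
#'   per clade: `clade`, `n_seq`, `omega_m0`, `p_m8`, `skip_reason`,
#'   `n_selected_branches`, `selected`) and per-clade `details`.
#' @export
run_cascade <- function(clade_alignments, clade_trees, omega_gate = 0.3,
                        alpha = 0.05, q_threshold = 0.05,
                        site_posterior = 0.95) {
  stopifnot(identical(sort(names(clade_alignments)),
                      sort(names(clade_trees))))
  details <- list()
  rows <- list()
  for (clade in names(clade_alignments)) {
    aln <- clade_alignments[[clade]]
    tree <- clade_trees[[clade]]
    m0 <- fit_m0(aln, tree)
    row <- data.frame(clade = clade, n_seq = nrow(aln),
                      omega_m0 = m0$omega, p_m8 = NA_real_,
                      skip_reason = NA_character_,
                      n_selected_branches = 0L, selected = "",
                      stringsAsFactors = FALSE)
    det <- list(m0 = m0)
    if (m0$omega <= omega_gate) {
      row$skip_reason <- sprintf(
        "omega_m0 = %.5f <= gate %.2f: site test skipped", m0$omega,
        omega_gate)
    } else {
      m8 <- fit_m8_pair(aln, tree, m0 = m0)
      det$m8 <- m8
      row$p_m8 <- m8$p_value
      if (m8$p_value >= alpha) {
        row$skip_reason <- sprintf(
          "M8 vs M8a p = %.4g >= alpha %.2f: branch tests skipped",
          m8$p_value, alpha)
      } else {
        term_edges <- which(tree$edge[, 2] <= ape::Ntip(tree))
        bs <- lapply(term_edges, function(e)
          fit_branch_site(aln, tree, e, m0 = m0,
                          site_posterior = site_posterior))
        pvals <- vapply(bs, `[[`, numeric(1), "p_value")
        qvals <- fdr_qvalue(pvals)
        branch_tab <- data.frame(
          branch = tree$tip.label[tree$edge[term_edges, 2]],
          edge = term_edges, p_value = pvals, q_value = qvals,
          n_sites = vapply(bs, function(b) length(b$selected_sites),
                           integer(1)),
          stringsAsFactors = FALSE)
        branch_tab$selected <- branch_tab$q_value < q_threshold
        det$branch_tests <- bs
        det$branches <- branch_tab
        sel <- branch_tab$branch[branch_tab$selected]
        row$n_selected_branches <- length(sel)
        row$selected <- paste(sel, collapse = ",")
        if (!length(sel))
          row$skip_reason <- sprintf(
            "all branch q-values >= %.2f: no positively selected gene",
            q_threshold)
      }
    }
    details[[clade]] <- det
    rows[[clade]] <- row
  }
  structure(list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
                 details = details,
                 thresholds = list(omega_gate = omega_gate, alpha = alpha,
                                   q_threshold = q_threshold)),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Selection-screen cascade (gate omega >",
      x$thresholds$omega_gate, ")\n")
  s <- x$summary
  s$p_m8 <- ifelse(is.na(s$p_m8), "/", signif(s$p_m8, 4))
  print(s[, c("clade", "n_seq", "omega_m0", "p_m8", "selected")],
        row.names = FALSE)
  invisible(x)
}
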