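# LCA-mapping duplication-loss reconciliation of a rooted binary gene tree
# with a rooted binary species tree: per-branch gains and losses, ancestral
# repertoire sizes, and the parsimony duplication+loss cost.

# -- small rooted-tree helpers on ape::phylo ---------------------------------

phylo_parents <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  parent <- rep(NA_integer_, n)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  parent
}

phylo_children <- function(tree) {
  n <- ape::Ntip(tree) + tree$Nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

phylo_depths <- function(tree, parent = phylo_parents(tree)) {
  n <- length(parent)
  root <- which(is.na(parent))
  depth <- rep(NA_integer_, n)
  depth[root] <- 0L
  # edges in tree$edge are not guaranteed topologically ordered; iterate
  repeat {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    for (v in todo) if (!is.na(depth[parent[v]])) depth[v] <- depth[parent[v]] + 1L
  }
  depth
}

check_binary_rooted <- function(tree, what) {
  if (!ape::is.rooted(tree)) stop(what, " must be rooted")
  kids <- phylo_children(tree)
  deg <- lengths(kids)
  internal <- which(deg > 0)
  if (any(deg[internal] != 2L))
    stop(what, " must be fully binary (node with ",
         paste(unique(deg[internal][deg[internal] != 2L]), collapse = "/"),
         " children found)")
  invisible(TRUE)
}

# ancestor (or equal) test using depths + parent pointers
is_ancestor_or_equal <- function(anc, node, parent, depth) {
  while (!is.na(node) && depth[node] > depth[anc]) node <- parent[node]
  !is.na(node) && node == anc
}

lca_pair <- function(a, b, parent, depth) {
  while (a != b) {
    if (depth[a] >= depth[b]) a <- parent[a] else b <- parent[b]
  }
  a
}

#' LCA mapping of a gene tree onto a species tree
#'
#' Maps every gene-tree node to a species-tree node: leaves map to their
#' species (via the prefix map), internal nodes to the lowest common
#' ancestor of their children's images.
#'
#' @param gene_tree,species_tree rooted binary `ape::phylo` trees.
#' @param prefix_map named character vector translating gene-id prefixes to
#'   species-tree tip labels (see [species_of_leaf()]).
#' @return integer vector `node_map` over gene-tree node indices giving the
#'   mapped species-tree node index, with attribute `"species_labels"`
#'   naming every species node (tip labels for tips, `node_label` or
#'   `"node<N>"` for internal nodes).
#' @export
lca_map <- function(gene_tree, species_tree, prefix_map) {
  check_binary_rooted(gene_tree, "gene tree")
  check_binary_rooted(species_tree, "species tree")
  sp_parent <- phylo_parents(species_tree)
  sp_depth <- phylo_depths(species_tree, sp_parent)
  sp_of_leaf <- species_of_leaf(gene_tree$tip.label, prefix_map)
  tip_idx <- match(sp_of_leaf, species_tree$tip.label)
  if (anyNA(tip_idx))
    stop("species not in species tree: ",
         paste(unique(sp_of_leaf[is.na(tip_idx)]), collapse = ", "))
  ng <- ape::Ntip(gene_tree) + gene_tree$Nnode
  M <- rep(NA_integer_, ng)
  M[seq_len(ape::Ntip(gene_tree))] <- tip_idx
  kids <- phylo_children(gene_tree)
  g_depth <- phylo_depths(gene_tree)
  for (v in order(g_depth, decreasing = TRUE)) {
    ch <- kids[[v]]
    if (length(ch) == 0L) next
    M[v] <- lca_pair(M[ch[1]], M[ch[2]], sp_parent, sp_depth)
  }
  attr(M, "species_labels") <- species_node_labels(species_tree)
  M
}

species_node_labels <- function(species_tree) {
  ns <- ape::Ntip(species_tree) + species_tree$Nnode
  lab <- character(ns)
  lab[seq_len(ape::Ntip(species_tree))] <- species_tree$tip.label
  inner <- if (!is.null(species_tree$node.label) &&
               any(nzchar(species_tree$node.label)))
    species_tree$node.label else NULL
  for (v in seq(ape::Ntip(species_tree) + 1L, ns)) {
    i <- v - ape::Ntip(species_tree)
    lab[v] <- if (!is.null(inner) && nzchar(inner[i])) inner[i]
              else paste0("node", v)
  }
  lab
}

#' Duplication-loss reconciliation
#'
#' Standard parsimony reconciliation under the LCA mapping: a gene node is a
#' duplication when it maps to the same species node as one of its children;
#' losses are counted along the species-tree path skipped by each gene edge.
#' Per-branch gains are duplications assigned to their mapped species node
#' (duplications mapping to the species root are reported on a stem branch
#' above it). `dl_cost` = duplications + losses on gene-tree edges, which is
#' minimal over all reconciliation scenarios. When the gene-tree root maps
#' below the species root, losses implied on the origination path (species
#' root down to the root's image) are reported in the per-branch loss table
#' (so ancestral counts are conserved) but, following the usual parsimony
#' convention, are not part of `dl_cost`.
#'
#' @inheritParams lca_map
#' @return object of class `reconciliation`: list with `node_map`,
#'   `duplications` (gene node indices), `gains` / `losses` (per species
#'   node: events on the branch leading into that node; the species root row
#'   is its stem branch), `ancestral_count` (per species node, lineages
#'   present after duplications at that node), `dl_cost`, `events` (per
#'   species node data.frame), and the input trees.
#' @export
reconcile <- function(gene_tree, species_tree, prefix_map) {
  M <- lca_map(gene_tree, species_tree, prefix_map)
  sp_parent <- phylo_parents(species_tree)
  sp_depth <- phylo_depths(species_tree, sp_parent)
  sp_kids <- phylo_children(species_tree)
  sp_root <- which(is.na(sp_parent))
  ns <- length(sp_parent)

  g_parent <- phylo_parents(gene_tree)
  g_kids <- phylo_children(gene_tree)
  g_root <- which(is.na(g_parent))
  ng <- length(g_parent)

  is_dup <- rep(FALSE, ng)
  for (v in seq_len(ng)) {
    ch <- g_kids[[v]]
    if (length(ch) && any(M[ch] == M[v])) is_dup[v] <- TRUE
  }

  losses <- rep(0L, ns)   # losses on the branch leading into species node s
  edge_losses <- 0L       # losses on gene-tree edges only (dl_cost part)
  count_path_losses <- function(top, bottom, passes_top) {
    # lineage travels from species node `top` down to `bottom`; at every
    # speciation it passes through, the sibling copy is lost
    path <- bottom
    while (path[1] != top) path <- c(sp_parent[path[1]], path)
    k <- length(path) - 1L
    if (k == 0L) return(0L)
    from <- if (passes_top) 1L else 2L
    nl <- 0L
    if (length(path) >= from + 1L) {
      for (i in seq(from, k)) {
        s <- path[i]; nxt <- path[i + 1L]
        sib <- setdiff(sp_kids[[s]], nxt)
        losses[sib] <<- losses[sib] + 1L
        nl <- nl + 1L
      }
    }
    nl
  }
  for (v in seq_len(ng)) {
    u <- g_parent[v]
    if (is.na(u)) next
    edge_losses <- edge_losses +
      count_path_losses(M[u], M[v], passes_top = is_dup[u])
  }
  # origination path: the single ancestral lineage enters at the species
  # root and descends to the gene root's image, shedding sibling copies
  count_path_losses(sp_root, M[g_root], passes_top = TRUE)

  gains <- rep(0L, ns)
  dup_nodes <- which(is_dup)
  for (v in dup_nodes) gains[M[v]] <- gains[M[v]] + 1L

  # ancestral counts by the conservation recurrence, origination count 1
  counts <- rep(NA_integer_, ns)
  counts[sp_root] <- 1L + gains[sp_root] - 0L
  for (s in order(sp_depth)) {
    if (s == sp_root) next
    counts[s] <- counts[sp_parent[s]] + gains[s] - losses[s]
  }

  lab <- attr(M, "species_labels")
  events <- data.frame(
    species_node = lab,
    branch = ifelse(seq_len(ns) == sp_root, "stem",
                    paste0(lab[ifelse(is.na(sp_parent), sp_root, sp_parent)],
                           "->", lab)),
    gains = gains, losses = losses, count = counts,
    is_tip = seq_len(ns) <= ape::Ntip(species_tree),
    stringsAsFactors = FALSE)

  structure(list(node_map = M, duplications = dup_nodes,
                 gains = stats::setNames(gains, lab),
                 losses = stats::setNames(losses, lab),
                 ancestral_count = stats::setNames(counts, lab),
                 dl_cost = length(dup_nodes) + edge_losses,
                 events = events,
                 gene_tree = gene_tree, species_tree = species_tree),
            class = "reconciliation")
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("Duplication-loss reconciliation: %d duplications, %d losses (dl cost %d)\n",
              length(x$duplications), x$dl_cost - length(x$duplications),
              x$dl_cost))
  print(x$events[, c("species_node", "gains", "losses", "count")],
        row.names = FALSE)
  invisible(x)
}

#' Ancestral repertoire sizes from a reconciliation
#'
#' Number of gene lineages present at each species node (after duplications
#' mapped to that node). At a tip this equals the species' observed
#' repertoire size; along every species branch the conservation identity
#' `count(child) = count(parent) + gains - losses` holds.
#'
#' @param result a [reconcile()] object.
#' @return named integer vector over species nodes.
#' @export
ancestral_counts <- function(result) {
  stopifnot(inherits(result, "reconciliation"))
  result$ancestral_count
}
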