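# LCA reconciliation of a gene tree against a species tree: event labelling,
# per-edge loss counts, duplication confidence scores and duplication-loss
# parsimony rooting.

#' Reconcile a rooted gene tree with a species tree
#'
#' Standard LCA reconciliation: each leaf maps to its species; each internal
#' node maps to the species-tree LCA of its children's mappings. An internal
#' node is a duplication iff its mapping equals the mapping of at least one
#' child, otherwise a speciation. Nodes mapped to a *multifurcating* taxon
#' (e.g. a flattened clade, whose branching order is unresolved) are instead
#' called duplications only when two child subtrees share a species, so that
#' splits compatible with some resolution of the multifurcation are not
#' over-called as duplications. Losses are counted per edge (see
#' [count_losses()]); a duplication confidence score (DCS) — the
#' intersection-over-union of the species sets of the node's child subtrees —
#' is attached to every duplication node.
#'
#' @param gene_tree a rooted [gene_tree()] with species ids on all leaves.
#' @param species_tree a [species_tree()] covering all leaf species.
#' @return an object of class `reconciliation`: a list with elements
#'   `tree` (the input tree annotated with `event`, `taxon` and `dcs`),
#'   `mapping` (species-tree node index per gene-tree node), `events`,
#'   `losses` (per edge above each node), `total_dup` and `total_loss`.
#' @export
reconcile <- function(gene_tree, species_tree) {
  gt <- gene_tree; st <- species_tree
  stopifnot(inherits(gt, "gene_tree"), inherits(st, "species_tree"))
  leaf <- is_leaf_node(gt)
  if (anyNA(gt$species[leaf]))
    stop("all gene-tree leaves need a species id (see set_species())")
  sidx <- st_leaf_index(st)
  missing <- setdiff(unique(gt$species[leaf]), names(sidx))
  if (length(missing))
    stop("species not in species tree: ", paste(missing, collapse = ", "))

  depth <- st_depths(st)
  n <- length(gt$parent)
  mapping <- integer(n)
  events <- rep(NA_character_, n)
  spsets <- clade_species(gt)

  multi <- lengths(st$children) > 2L
  for (v in postorder_nodes(gt)) {
    kids <- gt$children[[v]]
    if (!length(kids)) {
      mapping[v] <- sidx[[gt$species[v]]]
    } else {
      mapping[v] <- st_lca(st, depth, mapping[kids])
      dup <- if (multi[mapping[v]]) {
        # a multifurcating taxon represents unresolved branching order: call
        # a duplication only when two child subtrees share a species
        spsets_overlap(spsets[kids])
      } else {
        any(mapping[kids] == mapping[v])
      }
      events[v] <- if (dup) "duplication" else "speciation"
    }
  }

  losses <- numeric(n)
  for (v in seq_len(n)) {
    p <- gt$parent[v]
    if (p == 0L) next
    losses[v] <- edge_losses(depth, mapping[p], mapping[v],
                             events[p] == "duplication")
  }

  dcs <- rep(NA_real_, n)
  for (v in which(events == "duplication")) {
    dcs[v] <- dcs_value(spsets[gt$children[[v]]])
  }

  tax_label <- st$label[mapping]
  tax_label[!nzchar(tax_label)] <- paste0("stnode", mapping[!nzchar(tax_label)])
  gt$event <- events
  gt$taxon <- ifelse(leaf, NA_character_, tax_label)
  gt$dcs <- dcs

  structure(list(tree = gt, mapping = mapping, events = events,
                 losses = losses,
                 total_dup = sum(events == "duplication", na.rm = TRUE),
                 total_loss = sum(losses)),
            class = "reconciliation")
}

# losses on the edge m(parent) -> m(child): one loss per species-tree level
# passed through, plus one for the duplicated-but-absent lineage when the
# parent is a duplication mapped above the child
edge_losses <- function(depth, m_parent, m_child, parent_is_dup) {
  pl <- depth[m_child] - depth[m_parent]
  if (pl == 0L) return(0)
  max(0, pl - 1 + as.integer(isTRUE(parent_is_dup)))
}

spsets_overlap <- function(sets) {
  for (a in seq_along(sets)) {
    for (b in seq_along(sets)) {
      if (a < b && length(intersect(sets[[a]], sets[[b]]))) return(TRUE)
    }
  }
  FALSE
}

dcs_value <- function(child_sets) {
  inter <- Reduce(intersect, child_sets)
  uni <- Reduce(union, child_sets)
  length(inter) / length(uni)
}

#' Losses inferred on one gene-tree edge
#'
#' The number of gene losses implied on the edge from `node`'s parent down to
#' `node`: the number of species-tree levels crossed minus one, plus one
#' extra loss when the parent is a duplication whose second copy is absent
#' below `node`; zero when parent and child map to the same taxon.
#'
#' @param reconciliation a [reconcile()] result.
#' @param node gene-tree node index (non-root).
#' @return non-negative number of losses.
#' @export
count_losses <- function(reconciliation, node) {
  stopifnot(inherits(reconciliation, "reconciliation"))
  node <- as.integer(node)
  gt <- reconciliation$tree
  if (node < 1L || node > length(gt$parent)) stop("invalid node index")
  if (gt$parent[node] == 0L) stop("the root has no parent edge")
  reconciliation$losses[node]
}

#' Duplication confidence score of a node
#'
#' DCS = |species(left subtree) intersect species(right subtree)| /
#' |species(left) union species(right)|, i.e. the fraction of involved
#' species in which the duplication is observed in both daughter lineages.
#' Species-specific duplications score 1 by definition; a score of 0 arises
#' only when the gene tree and species tree disagree.
#'
#' @param reconciliation a [reconcile()] result.
#' @param node index of a duplication node.
#' @return a value in \[0, 1\].
#' @export
duplication_confidence <- function(reconciliation, node) {
  stopifnot(inherits(reconciliation, "reconciliation"))
  gt <- reconciliation$tree
  node <- as.integer(node)
  if (is.na(gt$event[node]) || !gt$event[node] %in% c("duplication", "dubious"))
    stop("node ", node, " is not a duplication node")
  dcs_value(clade_species(gt)[gt$children[[node]]])
}

#' Relabel weak duplications as dubious
#'
#' Duplication nodes with DCS below `threshold` are relabelled `"dubious"` in
#' the annotated tree for reporting; reconciliation totals still count them
#' as duplications.
#'
#' @param reconciliation a [reconcile()] result.
#' @param threshold DCS threshold (default 0.25).
#' @return the reconciliation with an updated annotated tree.
#' @export
flag_dubious <- function(reconciliation, threshold = 0.25) {
  stopifnot(inherits(reconciliation, "reconciliation"))
  gt <- reconciliation$tree
  weak <- !is.na(gt$event) & gt$event == "duplication" &
    !is.na(gt$dcs) & gt$dcs < threshold
  gt$event[weak] <- "dubious"
  reconciliation$tree <- gt
  reconciliation
}

#' Root a gene tree by duplication-loss parsimony
#'
#' Evaluates every possible rooting (one per unrooted edge), reconciles each
#' against the species tree, and returns the rooting minimising
#' total duplications + total losses. Only the topology is used; branch
#' lengths are ignored for scoring. Ties are broken deterministically by the
#' lexicographically smallest sorted gene list on the smaller side of the
#' root bipartition.
#'
#' @param tree a [gene_tree()] (rooted arbitrarily or not) with >= 3 leaves
#'   recommended; smaller trees are returned unchanged.
#' @param species_tree a [species_tree()].
#' @return a rooted [gene_tree()] with a binary root.
#' @export
root_by_dl <- function(tree, species_tree) {
  if (n_leaves(tree) < 3L) return(tree)
  best <- NULL
  for (v in rooting_candidates(tree)) {
    rt <- reroot_above(tree, v)
    rec <- reconcile(rt, species_tree)
    score <- rec$total_dup + rec$total_loss
    key <- root_split_tiekey(rt)
    if (is.null(best) || score < best$score ||
        (score == best$score && key < best$key)) {
      best <- list(tree = rt, score = score, key = key)
    }
  }
  best$tree
}

# deterministic tie-break key: sorted gene list of the smaller root side
root_split_tiekey <- function(tree) {
  kids <- tree$children[[tree$root]]
  sets <- clade_genes(tree)
  sides <- lapply(kids, function(k) sort(sets[[k]]))
  keys <- vapply(sides, paste, character(1), collapse = ",")
  sz <- lengths(sides)
  pick <- which(sz == min(sz))
  min(keys[pick])
}

# reconciliation score (dup + loss) of a rooted tree; internal helper
dl_score <- function(tree, species_tree) {
  rec <- reconcile(tree, species_tree)
  rec$total_dup + rec$total_loss
}

#' Tabulate reconciliation events
#'
#' @param reconciliation a [reconcile()] result.
#' @return a data.frame with one row per internal node: `node`, `event`,
#'   `taxon`, `dcs`, `losses` (losses on the edge above the node).
#' @export
event_table <- function(reconciliation) {
  gt <- reconciliation$tree
  internal <- which(!is_leaf_node(gt))
  data.frame(node = internal,
             event = gt$event[internal],
             taxon = gt$taxon[internal],
             dcs = gt$dcs[internal],
             losses = reconciliation$losses[internal],
             stringsAsFactors = FALSE)
}

#' @export
print.reconciliation <- function(x, ...) {
  cat(sprintf("reconciliation: %d leaves, %d duplications, %g losses\n",
              n_leaves(x$tree), x$total_dup, x$total_loss))
  invisible(x)
}
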