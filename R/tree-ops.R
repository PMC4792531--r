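# Basic topological operations on gene trees: induced subtrees, bipartition
# extraction and rerooting along edges.

#' Restrict a gene tree to a subset of its genes
#'
#' Returns the subtree induced by `genes`. Internal nodes left with a single
#' child are suppressed, with the branch lengths of the collapsed chain summed
#' onto the retained node; the retained node keeps its own bootstrap and other
#' annotations.
#'
#' @param tree a [gene_tree()].
#' @param genes character vector of gene ids (subset of the leaf set, at
#'   least one).
#' @return a [gene_tree()] whose leaf set is exactly `genes`.
#' @export
restrict <- function(tree, genes) {
  stopifnot(inherits(tree, "gene_tree"))
  genes <- unique(as.character(genes))
  if (!length(genes)) stop("need at least one gene")
  unknown <- setdiff(genes, leaf_genes(tree))
  if (length(unknown))
    stop("unknown gene_id(s): ", paste(unknown, collapse = ", "))

  keep <- !is.na(tree$gene) & tree$gene %in% genes
  has_kept <- logical(length(tree$parent))
  for (v in postorder_nodes(tree)) {
    kids <- tree$children[[v]]
    has_kept[v] <- if (length(kids)) any(has_kept[kids]) else keep[v]
  }

  tb <- tb_new()
  rec <- function(v, parent_new, carry) {
    kids <- tree$children[[v]]
    if (!length(kids)) {
      do.call(tb_add, c(list(tb, parent_new, len_sum(tree$length[v], carry)),
                        node_fields(tree, v)))
      return(invisible(NULL))
    }
    live <- kids[has_kept[kids]]
    if (length(live) == 1L) {
      # suppress v: its edge length is added to the retained child's edge
      rec(live, parent_new, len_sum(carry, tree$length[v]))
    } else {
      id <- do.call(tb_add, c(list(tb, parent_new,
                                   len_sum(tree$length[v], carry)),
                              node_fields(tree, v)))
      for (c in live) rec(c, id, NA_real_)
    }
    invisible(NULL)
  }
  rec(tree$root, 0L, NA_real_)
  tb_gene_tree(tb)
}

split_key <- function(side) paste(sort(side), collapse = "|")

#' Bipartitions of a tree
#'
#' One bipartition per unrooted branch: each node's clade versus the rest of
#' the leaf set, canonicalized so that the reported side is the one *not*
#' containing the alphabetically first leaf. For a binary root the two root
#' edges describe the same unrooted branch and are merged (lengths summed).
#'
#' @param tree a [gene_tree()] or [species_tree()] with at least 2 leaves.
#' @param trivial include the trivial single-leaf splits?
#' @return a data.frame with columns `split` (canonical `|`-separated side),
#'   `size` (number of leaves on that side) and `length` (branch length, `NA`
#'   if absent).
#' @export
bipartitions <- function(tree, trivial = FALSE) {
  if (n_leaves(tree) < 2L) stop("tree must have at least 2 leaves")
  if (inherits(tree, "species_tree")) {
    labels_of <- function(v) sets[[v]]
    sets <- {
      s <- vector("list", length(tree$parent))
      for (v in postorder_nodes(tree)) {
        kids <- tree$children[[v]]
        s[[v]] <- if (length(kids)) unlist(s[kids], use.names = FALSE)
                  else tree$label[v]
      }
      s
    }
    all_lv <- sort(unlist(sets[[tree$root]]))
  } else {
    sets <- clade_genes(tree)
    all_lv <- sort(leaf_genes(tree))
  }
  ref <- all_lv[1L]
  nl <- length(all_lv)
  keys <- character(0); sizes <- integer(0); lens <- numeric(0)
  for (v in seq_along(tree$parent)) {
    if (v == tree$root) next
    s <- sets[[v]]
    side <- if (ref %in% s) setdiff(all_lv, s) else s
    if (!length(side) || length(side) == nl) next
    if (!trivial && (length(side) < 2L || nl - length(side) < 2L)) next
    keys <- c(keys, split_key(side))
    sizes <- c(sizes, length(side))
    lens <- c(lens, tree$length[v])
  }
  if (!length(keys)) {
    return(data.frame(split = character(0), size = integer(0),
                      length = numeric(0), stringsAsFactors = FALSE))
  }
  # merge duplicate entries arising from the two edges of a binary root
  agg_len <- tapply(lens, keys, function(x) {
    if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
  })
  agg_size <- tapply(sizes, keys, function(x) x[1L])
  data.frame(split = names(agg_len), size = as.integer(agg_size),
             length = as.numeric(agg_len), row.names = NULL,
             stringsAsFactors = FALSE)
}

# candidate edges for rooting: every non-root node; for a binary root the two
# root edges coincide, keep only the first
rooting_candidates <- function(tree) {
  kids <- tree$children[[tree$root]]
  cand <- setdiff(seq_along(tree$parent), tree$root)
  if (length(kids) == 2L) cand <- setdiff(cand, kids[2L])
  cand
}

#' Reroot a gene tree on the edge above a node
#'
#' Places a new root in the middle of the edge between `node` and its parent
#' (the edge length, when present, is halved on each side). The former root is
#' suppressed if it is left with a single child. Edge annotations (lengths,
#' bootstraps) follow their unrooted edges.
#'
#' @param tree a [gene_tree()].
#' @param node index of a non-root node.
#' @return a [gene_tree()] with a binary root.
#' @export
reroot_above <- function(tree, node) {
  v <- as.integer(node)
  if (v == tree$root) stop("cannot reroot above the root")
  p <- tree$parent[v]
  root <- tree$root
  if (p == root && length(tree$children[[root]]) == 2L) return(tree)

  n <- length(tree$parent)
  parent <- tree$parent; len <- tree$length; boot <- tree$bootstrap
  old_len <- tree$length; old_boot <- tree$bootstrap
  # path from v's parent up to the old root
  path <- integer(0); w <- p
  while (w != 0L) { path <- c(path, w); w <- tree$parent[w] }

  R <- n + 1L  # new root
  parent <- c(parent, 0L); len <- c(len, NA_real_); boot <- c(boot, NA_real_)
  half <- if (is.na(old_len[v])) NA_real_ else old_len[v] / 2
  parent[v] <- R; len[v] <- half
  parent[p] <- R; len[p] <- half; boot[p] <- old_boot[v]
  if (length(path) > 1L) {
    for (i in seq_len(length(path) - 1L)) {
      child <- path[i + 1L]; par <- path[i]
      parent[child] <- par
      len[child] <- old_len[par]
      boot[child] <- old_boot[par]
    }
  }

  # assemble extended node table, then rebuild (possibly splicing the old root)
  ext <- list(parent = parent, length = len,
              label = c(tree$label, ""), gene = c(tree$gene, NA_character_),
              species = c(tree$species, NA_character_), bootstrap = boot,
              event = c(tree$event, NA_character_),
              taxon = c(tree$taxon, NA_character_),
              dcs = c(tree$dcs, NA_real_),
              supporters = c(tree$supporters, list(NULL)))
  children <- build_children(ext$parent)

  # splice the old root if unary
  if (length(children[[root]]) == 1L) {
    c_rem <- children[[root]]
    ext$parent[c_rem] <- ext$parent[root]
    ext$length[c_rem] <- len_sum(ext$length[c_rem], ext$length[root])
    if (is.na(ext$bootstrap[c_rem])) ext$bootstrap[c_rem] <- ext$bootstrap[root]
    ext$parent[root] <- -1L  # mark removed
    children <- build_children(pmax(ext$parent, 0L))
  }

  tb <- tb_new()
  walk <- function(old_id, parent_new) {
    id <- tb_add(tb, parent_new, ext$length[old_id], ext$label[old_id],
                 ext$gene[old_id], ext$species[old_id], ext$bootstrap[old_id],
                 ext$event[old_id], ext$taxon[old_id], ext$dcs[old_id],
                 ext$supporters[[old_id]])
    for (c in children[[old_id]]) walk(c, id)
    id
  }
  walk(R, 0L)
  tb_gene_tree(tb)
}
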