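# Species-tree utilities: depths, LCA queries, clade flattening.

st_depths <- function(st) {
  d <- integer(length(st$parent))
  for (v in preorder_nodes(st)) {
    p <- st$parent[v]
    d[v] <- if (p == 0L) 0L else d[p] + 1L
  }
  d
}

st_lca2 <- function(st, depth, a, b) {
  while (depth[a] > depth[b]) a <- st$parent[a]
  while (depth[b] > depth[a]) b <- st$parent[b]
  while (a != b) { a <- st$parent[a]; b <- st$parent[b] }
  a
}

st_lca <- function(st, depth, nodes) {
  nodes <- unique(nodes)
  Reduce(function(a, b) st_lca2(st, depth, a, b), nodes)
}

# named integer vector: species name -> leaf node index
st_leaf_index <- function(st) {
  leaf <- which(is_leaf_node(st))
  stats::setNames(leaf, st$label[leaf])
}

st_node_by_label <- function(st, name) {
  hit <- which(st$label == name)
  if (length(hit) != 1L) stop("unknown taxon name: ", name)
  hit
}

# leaf taxon names under every node
st_clade_taxa <- function(st) {
  sets <- vector("list", length(st$parent))
  for (v in postorder_nodes(st)) {
    kids <- st$children[[v]]
    sets[[v]] <- if (length(kids)) unlist(sets[kids], use.names = FALSE)
                 else st$label[v]
  }
  sets
}

#' Flatten named clades of a species tree
#'
#' Each named clade is collapsed to a single multifurcating node whose
#' children are the clade's leaves. Flattening densely sampled clades gives
#' the reconciliation more freedom within them and avoids over-calling
#' duplication nodes caused by unresolved or erroneous within-clade topology.
#'
#' @param st a [species_tree()].
#' @param clades character vector of internal taxon names to flatten.
#' @return a [species_tree()] with the same leaf set.
#' @export
simplify_species_tree <- function(st, clades) {
  idx <- vapply(clades, function(nm) st_node_by_label(st, nm), integer(1))
  taxa <- st_clade_taxa(st)
  flat <- logical(length(st$parent))
  flat[idx] <- TRUE
  tb <- tb_new()
  rec <- function(v, parent_new) {
    id <- tb_add(tb, parent_new, st$length[v], st$label[v])
    if (flat[v]) {
      for (lv in taxa[[v]]) tb_add(tb, id, NA_real_, lv)
    } else {
      for (c in st$children[[v]]) rec(c, id)
    }
    id
  }
  rec(st$root, 0L)
  tb_species_tree(tb)
}

#' Example vertebrate-like species trees
#'
#' Small fixed species trees used throughout the examples, tests and the
#' synthetic benchmark. `example_species_tree(n)` returns a balanced-ish
#' binary tree over taxa `A`, `B`, ... with unit branch lengths and named
#' internal nodes.
#'
#' @param n number of taxa (2..26).
#' @return a [species_tree()].
#' @export
example_species_tree <- function(n = 8) {
  stopifnot(n >= 2, n <= 26)
  taxa <- LETTERS[seq_len(n)]
  # caterpillar-free balanced construction via recursive halving
  build <- function(tx) {
    if (length(tx) == 1L) return(tx)
    k <- ceiling(length(tx) / 2)
    paste0("(", build(tx[seq_len(k)]), ":1,",
           build(tx[-seq_len(k)]), ":1)", paste(tx, collapse = ""))
  }
  parse_newick(paste0(build(taxa), ";"), type = "species")
}
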