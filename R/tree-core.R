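# ---- internal tree representation -------------------------------------------
#
# Both tree classes store nodes as parallel vectors indexed 1..n:
#   parent   integer, 0 for the root (exactly one root)
#   length   numeric branch length of the edge ABOVE the node (NA allowed)
#   label    character node label ("" when absent)
# gene trees additionally carry per-node:
#   gene, species, bootstrap, event, taxon, dcs, supporters (list column)
# children lists and the root index are derived at construction time.

build_children <- function(parent) {
  n <- length(parent)
  ch <- rep(list(integer(0)), n)
  for (i in seq_len(n)) {
    p <- parent[i]
    if (p > 0L) ch[[p]] <- c(ch[[p]], i)
  }
  ch
}

validate_parent <- function(parent) {
  n <- length(parent)
  if (n < 1L) stop("a tree needs at least one node")
  roots <- which(parent == 0L)
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (any(parent < 0L | parent > n)) stop("parent index out of range")
  # acyclicity: walking up from any node must terminate
  for (i in seq_len(n)) {
    v <- i; steps <- 0L
    while (v != 0L) {
      v <- parent[v]; steps <- steps + 1L
      if (steps > n) stop("cycle detected in parent links")
    }
  }
  roots
}

recycle_field <- function(x, n, default) {
  if (is.null(x)) x <- default
  if (length(x) == 1L) x <- rep(x, n)
  if (length(x) != n) stop("field length must be 1 or n")
  x
}

#' Construct a gene tree
#'
#' A gene tree is a rooted (possibly multifurcating) tree whose leaves carry a
#' gene identifier and, optionally, a species identifier. Internal nodes may
#' carry a bootstrap value, a reconciliation event label
#' (`"speciation"`, `"duplication"` or `"dubious"`), the species-tree taxon
#' they map to, a duplication confidence score and the list of input trees
#' supporting their branch.
#'
#' @param parent integer vector of parent indices; 0 marks the root.
#' @param length numeric branch lengths (edge above each node); `NA` allowed.
#' @param label node labels; leaf labels default to the gene ids.
#' @param gene,species per-leaf identifiers (`NA` on internal nodes).
#' @param bootstrap,event,taxon,dcs,supporters optional per-node annotations.
#' @return an object of class `gene_tree`.
#' @export
gene_tree <- function(parent, length = NA_real_, label = NA_character_,
                      gene = NULL, species = NA_character_,
                      bootstrap = NA_real_, event = NA_character_,
                      taxon = NA_character_, dcs = NA_real_,
                      supporters = NULL) {
  parent <- as.integer(parent)
  n <- length(parent)
  root <- validate_parent(parent)
  len <- recycle_field(as.numeric(length), n, NA_real_)
  if (any(!is.na(len) & len < 0)) stop("branch lengths must be non-negative")
  lab <- recycle_field(as.character(label), n, NA_character_)
  children <- build_children(parent)
  leaf <- lengths(children) == 0L
  gene <- recycle_field(as.character(gene %||% lab), n, NA_character_)
  gene[!leaf] <- NA_character_
  lab[leaf & is.na(lab)] <- gene[leaf & is.na(lab)]
  lab[is.na(lab)] <- ""
  lg <- gene[leaf]
  if (anyNA(lg)) stop("every leaf needs a gene id")
  if (anyDuplicated(lg)) stop("leaf gene ids must be unique")
  sup <- supporters %||% rep(list(NULL), n)
  if (length(sup) != n) stop("supporters must have one entry per node")
  tr <- list(parent = parent, children = children, root = root,
             length = len, label = lab, gene = gene,
             species = recycle_field(as.character(species), n, NA_character_),
             bootstrap = recycle_field(as.numeric(bootstrap), n, NA_real_),
             event = recycle_field(as.character(event), n, NA_character_),
             taxon = recycle_field(as.character(taxon), n, NA_character_),
             dcs = recycle_field(as.numeric(dcs), n, NA_real_),
             supporters = sup)
  class(tr) <- "gene_tree"
  tr
}

#' Construct a species tree
#'
#' Rooted, possibly multifurcating taxon tree. Branch lengths, when present,
#' are interpreted as time (millions of years) by the gain/loss model.
#'
#' @param parent integer parent indices (0 = root).
#' @param length numeric branch lengths or `NA`.
#' @param label taxon names; leaf labels are mandatory and must be unique.
#' @return an object of class `species_tree`.
#' @export
species_tree <- function(parent, length = NA_real_, label = NA_character_) {
  parent <- as.integer(parent)
  n <- length(parent)
  root <- validate_parent(parent)
  len <- recycle_field(as.numeric(length), n, NA_real_)
  lab <- recycle_field(as.character(label), n, NA_character_)
  lab[is.na(lab)] <- ""
  children <- build_children(parent)
  leaf <- lengths(children) == 0L
  if (any(!nzchar(lab[leaf]))) stop("every species-tree leaf needs a taxon name")
  named <- lab[nzchar(lab)]
  if (anyDuplicated(named)) stop("taxon names must be unique")
  tr <- list(parent = parent, children = children, root = root,
             length = len, label = lab)
  class(tr) <- "species_tree"
  tr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- traversal helpers ------------------------------------------------------

preorder_nodes <- function(tr) {
  n <- length(tr$parent)
  out <- integer(n); stack <- integer(n)
  sp <- 1L; stack[1L] <- tr$root; k <- 0L
  while (sp > 0L) {
    v <- stack[sp]; sp <- sp - 1L
    k <- k + 1L; out[k] <- v
    for (c in tr$children[[v]]) { sp <- sp + 1L; stack[sp] <- c }
  }
  out[seq_len(k)]
}

# reversed preorder: every node appears after all of its children
postorder_nodes <- function(tr) rev(preorder_nodes(tr))

is_leaf_node <- function(tr) lengths(tr$children) == 0L

#' Number of leaves of a tree
#' @param tree a `gene_tree` or `species_tree`.
#' @export
n_leaves <- function(tree) sum(is_leaf_node(tree))

#' Leaf gene identifiers of a gene tree
#' @param tree a `gene_tree`.
#' @export
leaf_genes <- function(tree) tree$gene[is_leaf_node(tree)]

#' Leaf species identifiers of a gene tree
#' @param tree a `gene_tree`.
#' @return character vector named by gene id.
#' @export
leaf_species <- function(tree) {
  leaf <- is_leaf_node(tree)
  stats::setNames(tree$species[leaf], tree$gene[leaf])
}

#' Is a tree fully binary?
#' @param tree a `gene_tree` or `species_tree`.
#' @export
is_binary <- function(tree) {
  k <- lengths(tree$children)
  all(k[k > 0L] == 2L)
}

#' Assign species to the leaves of a gene tree
#' @param tree a `gene_tree`.
#' @param map named character vector, gene id -> species id.
#' @export
set_species <- function(tree, map) {
  leaf <- which(is_leaf_node(tree))
  hit <- match(tree$gene[leaf], names(map))
  if (anyNA(hit)) {
    stop("no species mapping for gene(s): ",
         paste(tree$gene[leaf][is.na(hit)], collapse = ", "))
  }
  tree$species[leaf] <- unname(map[hit])
  tree
}

# leaf gene sets of every clade (list over nodes)
clade_genes <- function(tr) {
  ord <- postorder_nodes(tr)
  sets <- vector("list", length(tr$parent))
  for (v in ord) {
    kids <- tr$children[[v]]
    if (!length(kids)) sets[[v]] <- tr$gene[v]
    else sets[[v]] <- unlist(sets[kids], use.names = FALSE)
  }
  sets
}

clade_species <- function(tr) {
  ord <- postorder_nodes(tr)
  sets <- vector("list", length(tr$parent))
  for (v in ord) {
    kids <- tr$children[[v]]
    if (!length(kids)) sets[[v]] <- tr$species[v]
    else sets[[v]] <- unique(unlist(sets[kids], use.names = FALSE))
  }
  sets
}

len_sum <- function(a, b) {
  if (is.na(a) && is.na(b)) NA_real_ else sum(c(a, b), na.rm = TRUE)
}

# ---- incremental tree builder ----------------------------------------------

tb_new <- function() {
  e <- new.env(parent = emptyenv())
  e$parent <- integer(0); e$length <- numeric(0); e$label <- character(0)
  e$gene <- character(0); e$species <- character(0); e$bootstrap <- numeric(0)
  e$event <- character(0); e$taxon <- character(0); e$dcs <- numeric(0)
  e$supporters <- list()
  e
}

tb_add <- function(tb, parent, length = NA_real_, label = "",
                   gene = NA_character_, species = NA_character_,
                   bootstrap = NA_real_, event = NA_character_,
                   taxon = NA_character_, dcs = NA_real_, supporters = NULL) {
  id <- length(tb$parent) + 1L
  tb$parent[id] <- as.integer(parent)
  tb$length[id] <- as.numeric(length)
  tb$label[id] <- as.character(label)
  tb$gene[id] <- as.character(gene)
  tb$species[id] <- as.character(species)
  tb$bootstrap[id] <- as.numeric(bootstrap)
  tb$event[id] <- as.character(event)
  tb$taxon[id] <- as.character(taxon)
  tb$dcs[id] <- as.numeric(dcs)
  tb$supporters[id] <- list(supporters)
  id
}

tb_gene_tree <- function(tb) {
  gene_tree(parent = tb$parent, length = tb$length, label = tb$label,
            gene = tb$gene, species = tb$species, bootstrap = tb$bootstrap,
            event = tb$event, taxon = tb$taxon, dcs = tb$dcs,
            supporters = tb$supporters)
}

tb_species_tree <- function(tb) {
  species_tree(parent = tb$parent, length = tb$length, label = tb$label)
}

# copy the annotation fields of node v of `tree` as a tb_add argument list
node_fields <- function(tree, v) {
  list(label = tree$label[v], gene = tree$gene[v], species = tree$species[v],
       bootstrap = tree$bootstrap[v], event = tree$event[v],
       taxon = tree$taxon[v], dcs = tree$dcs[v],
       supporters = tree$supporters[[v]])
}

#' @export
print.gene_tree <- function(x, ...) {
  cat(sprintf("gene_tree: %d leaves, %d nodes%s\n", n_leaves(x),
              length(x$parent), if (is_binary(x)) " (binary)" else ""))
  nw <- write_newick(x)
  if (nchar(nw) > 200) nw <- paste0(substr(nw, 1, 200), "...")
  cat(nw, "\n")
  invisible(x)
}

#' @export
print.species_tree <- function(x, ...) {
  cat(sprintf("species_tree: %d taxa, %d nodes\n", n_leaves(x), length(x$parent)))
  nw <- write_newick(x)
  if (nchar(nw) > 200) nw <- paste0(substr(nw, 1, 200), "...")
  cat(nw, "\n")
  invisible(x)
}
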