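# Handling of large gene families: p-distances from an alignment, an NJ guide
# tree, recursive splitting into bounded-size clusters, supertree reassembly
# and the fast-mode size trigger.

#' Pairwise p-distance matrix from a multiple alignment
#'
#' Proportion of mismatching sites over the columns where both sequences are
#' ungapped. Pairs with no comparable column are assigned the matrix maximum.
#'
#' @param alignment a named character vector of equal-length aligned
#'   sequences, a character matrix (rows = sequences), or the path to a
#'   FASTA file.
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    fa <- seqinr::read.fasta(alignment, as.string = TRUE, forceDNAtolower = FALSE)
    alignment <- stats::setNames(vapply(fa, as.character, character(1)),
                                 names(fa))
  }
  if (is.matrix(alignment)) {
    mat <- toupper(alignment)
  } else {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L)
      stop("ragged alignment: sequences differ in length")
    mat <- t(vapply(alignment, function(s) strsplit(toupper(s), "")[[1L]],
                    character(lens[1L])))
  }
  n <- nrow(mat)
  if (is.null(rownames(mat))) rownames(mat) <- paste0("seq", seq_len(n))
  gap <- mat == "-" | mat == "."
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  none <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) { none[i, j] <- none[j, i] <- TRUE; next }
      p <- mean(mat[i, ok] != mat[j, ok])
      d[i, j] <- d[j, i] <- p
    }
  }
  if (any(none)) {
    mx <- max(d)
    d[none] <- mx
  }
  d
}

#' Neighbour-joining guide tree
#'
#' Standard NJ agglomeration (via `ape::nj`) with negative estimated branch
#' lengths clamped to zero; used as the guide tree for splitting large
#' families.
#'
#' @param dist symmetric non-negative matrix with zero diagonal and at least
#'   3 rows, with row names naming the genes.
#' @return an unrooted (trifurcating-root) [gene_tree()].
#' @export
neighbor_joining <- function(dist) {
  dist <- as.matrix(dist)
  if (nrow(dist) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(dist))) stop("distance matrix must be finite")
  if (any(diag(dist) != 0)) stop("distance matrix must have zero diagonal")
  if (is.null(rownames(dist))) rownames(dist) <- paste0("seq", seq_len(nrow(dist)))
  phy <- ape::nj(stats::as.dist(dist))
  phy$edge.length[phy$edge.length < 0] <- 0
  from_phylo(phy, type = "gene")
}

#' Split a gene family guided by a tree
#'
#' Midpoint-roots the guide tree and descends from the root: any clade with
#' at most `max_size` genes becomes a cluster; larger clades are split into
#' their child clades recursively. The returned hierarchy records the cut
#' structure for later reassembly with [assemble_supertree()].
#'
#' @param genes character vector of the family's gene ids (must equal the
#'   guide-tree leaf set).
#' @param guide_tree a [gene_tree()] over `genes` (e.g. from
#'   [neighbor_joining()]).
#' @param max_size maximum genes per cluster (default 400).
#' @return an object of class `split_hierarchy`: a nested list of
#'   `list(type = "split", children = ...)` and
#'   `list(type = "cluster", genes = ...)` nodes.
#' @export
split_family <- function(genes, guide_tree, max_size = 400) {
  if (max_size < 1) stop("max_size must be >= 1")
  genes <- sort(unique(as.character(genes)))
  if (!identical(genes, sort(leaf_genes(guide_tree))))
    stop("guide tree leaf set must equal the gene set")
  if (length(genes) <= max_size) {
    h <- list(type = "cluster", genes = genes)
    class(h) <- "split_hierarchy"
    return(h)
  }
  rooted <- if (n_leaves(guide_tree) >= 3L) {
    from_phylo(phangorn::midpoint(as_phylo(guide_tree)), type = "gene")
  } else guide_tree
  rooted <- set_species_if_known(rooted, guide_tree)
  sets <- clade_genes(rooted)
  rec <- function(v) {
    s <- sets[[v]]
    if (length(s) <= max_size) return(list(type = "cluster", genes = sort(s)))
    kids <- rooted$children[[v]]
    if (!length(kids)) stop("cannot split a single gene further")
    list(type = "split", children = lapply(kids, rec))
  }
  h <- rec(rooted$root)
  class(h) <- "split_hierarchy"
  h
}

# carry species assignments through the ape round trip, when present
set_species_if_known <- function(new_tree, old_tree) {
  sp <- leaf_species(old_tree)
  if (all(is.na(sp))) return(new_tree)
  set_species(new_tree, sp)
}

#' Gene clusters of a split hierarchy
#' @param hierarchy a [split_family()] result.
#' @return named list of character vectors (`cluster1`, `cluster2`, ...).
#' @export
hierarchy_clusters <- function(hierarchy) {
  out <- list()
  rec <- function(h) {
    if (h$type == "cluster") out[[length(out) + 1L]] <<- h$genes
    else for (c in h$children) rec(c)
  }
  rec(hierarchy)
  stats::setNames(out, paste0("cluster", seq_along(out)))
}

#' Reassemble sub-trees into a supertree
#'
#' Replaces each cluster leaf of the hierarchy by its independently inferred
#' subtree. Connecting branches carry no length; the hierarchy root becomes
#' the supertree root.
#'
#' @param hierarchy a [split_family()] result.
#' @param subtrees named list of rooted [gene_tree()]s, one per cluster (in
#'   the order/naming of [hierarchy_clusters()]), with leaf sets matching the
#'   clusters.
#' @return a rooted [gene_tree()] over the full family.
#' @export
assemble_supertree <- function(hierarchy, subtrees) {
  clusters <- hierarchy_clusters(hierarchy)
  if (length(subtrees) != length(clusters))
    stop("need exactly one subtree per cluster")
  if (is.null(names(subtrees))) names(subtrees) <- names(clusters)
  for (nm in names(clusters)) {
    if (is.null(subtrees[[nm]]))
      stop("missing subtree for ", nm)
    if (!identical(sort(leaf_genes(subtrees[[nm]])), clusters[[nm]]))
      stop("subtree leaf set does not match ", nm)
  }
  if (length(clusters) == 1L) return(subtrees[[1L]])
  tb <- tb_new()
  k <- 0L
  graft <- function(tree, v, parent_new, top_len) {
    id <- do.call(tb_add, c(list(tb, parent_new,
                                 if (is.na(top_len)) tree$length[v] else top_len),
                            node_fields(tree, v)))
    for (c in tree$children[[v]]) graft(tree, c, id, NA_real_)
    id
  }
  rec <- function(h, parent_new) {
    if (h$type == "cluster") {
      k <<- k + 1L
      sub <- subtrees[[names(clusters)[k]]]
      graft(sub, sub$root, parent_new, NA_real_)
    } else {
      id <- tb_add(tb, parent_new, NA_real_)
      for (c in h$children) rec(c, id)
    }
    invisible(NULL)
  }
  rec(hierarchy, 0L)
  tb_gene_tree(tb)
}

#' Does a family require fast-mode tree building?
#'
#' Very large families (more than `threshold` base pairs of total input
#' sequence) are routed to faster alignment/tree-building alternatives.
#'
#' @param total_input_sequence_length total bases across the family.
#' @param threshold size trigger in base pairs (default 150000); the trigger
#'   is strict: exactly `threshold` bases does not enable fast mode.
#' @return logical.
#' @export
needs_fast_mode <- function(total_input_sequence_length, threshold = 150000) {
  stopifnot(total_input_sequence_length >= 0)
  total_input_sequence_length > threshold
}
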