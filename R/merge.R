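# Species-tree-aware merging of multiple candidate gene trees ("mmerge").
#
# The merge recursively divides the gene set in two. At each step the
# candidate bipartitions are those induced by the input trees restricted to
# the current gene set (the root split of each restriction, plus every
# child-versus-rest split when the restricted root is multifurcating). The
# chosen split (i) prefers speciation over duplication against the species
# tree, (ii) then minimises the losses on the two branches it creates,
# (iii) then maximises the best bootstrap among supporting input nodes and
# (iv) finally falls back to a deterministic lexicographic tie-break. The
# input trees supporting the chosen split are recorded on the branch.

#' Merge multiple gene trees into one reconciled binary tree
#'
#' @param input_trees named list of rooted [gene_tree()]s over the identical
#'   gene set (typically pre-rooted with [root_by_dl()]); names are the
#'   input-tree identifiers recorded as supporters.
#' @param species_tree a [species_tree()] covering all leaf species.
#' @return a binary rooted [gene_tree()], reconciled and annotated with
#'   `event`, `taxon`, `dcs` and per-branch `supporters`; branch lengths are
#'   the median lengths of the corresponding clades in the input trees
#'   (approximate, attribute `lengths = "median-of-inputs"`). The input-tree
#'   ids are stored in attribute `input_ids`.
#' @export
mmerge <- function(input_trees, species_tree) {
  stopifnot(length(input_trees) >= 1L)
  ids <- names(input_trees)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids))
    stop("input_trees must have unique non-empty names")
  st <- species_tree
  gsets <- lapply(input_trees, function(t) sort(leaf_genes(t)))
  for (i in seq_along(gsets)) {
    if (!identical(gsets[[i]], gsets[[1L]]))
      stop("input trees do not share the same gene set (",
           ids[i], " differs)")
  }
  genes <- gsets[[1L]]
  # gene -> species map, checked for consistency across inputs
  spmap <- leaf_species(input_trees[[1L]])
  for (t in input_trees[-1L]) {
    sp <- leaf_species(t)
    if (!identical(sp[names(spmap)], spmap))
      stop("inconsistent species assignments across input trees")
  }
  if (anyNA(spmap)) stop("all leaves need species ids")
  sidx <- st_leaf_index(st)
  missing <- setdiff(unique(spmap), names(sidx))
  if (length(missing))
    stop("species not in species tree: ", paste(missing, collapse = ", "))
  depth <- st_depths(st)
  gene_leaf <- sidx[spmap]          # gene id -> species-tree leaf index
  names(gene_leaf) <- names(spmap)

  lca_of_genes <- function(g) st_lca(st, depth, unname(gene_leaf[g]))

  multi <- lengths(st$children) > 2L
  # evaluate one candidate split (X vs Y) of gene set G
  eval_split <- function(X, Y) {
    mX <- lca_of_genes(X); mY <- lca_of_genes(Y)
    m <- st_lca2(st, depth, mX, mY)
    dup <- if (multi[m]) {
      length(intersect(unique(unname(spmap[X])),
                       unique(unname(spmap[Y])))) > 0L
    } else (m == mX) || (m == mY)
    loss <- edge_losses(depth, m, mX, dup) + edge_losses(depth, m, mY, dup)
    list(event = if (dup) "duplication" else "speciation", losses = loss,
         taxon_node = m)
  }

  # candidate splits of gene set G from the restricted input trees
  candidates <- function(G) {
    cand <- list()
    for (i in seq_along(input_trees)) {
      rtr <- restrict(input_trees[[i]], G)
      sets <- clade_genes(rtr)
      kids <- rtr$children[[rtr$root]]
      if (length(kids) < 2L) next
      if (length(kids) == 2L) {
        sides <- list(sets[[kids[1L]]])
        # the split's bootstrap lives on the restricted root (edge above it in
        # the original tree) or on either root edge
        boots <- max(c(rtr$bootstrap[rtr$root], rtr$bootstrap[kids], 0),
                     na.rm = TRUE)
        boots <- list(boots)
      } else {
        sides <- lapply(kids, function(k) sets[[k]])
        boots <- lapply(kids, function(k) {
          b <- rtr$bootstrap[k]; if (is.na(b)) 0 else b
        })
      }
      for (j in seq_along(sides)) {
        X <- sides[[j]]
        if (!length(X) || length(X) == length(G)) next
        key <- split_key(X)
        ckey <- split_key(setdiff(G, X))
        # canonical key: lexicographically smaller of the two side keys
        if (ckey < key) key <- ckey
        if (is.null(cand[[key]])) {
          cand[[key]] <- list(side = sort(X), supporters = ids[i],
                              boot = boots[[j]])
        } else {
          cand[[key]]$supporters <- union(cand[[key]]$supporters, ids[i])
          cand[[key]]$boot <- max(cand[[key]]$boot, boots[[j]])
        }
      }
    }
    cand
  }

  tiekey <- function(X, Y) {
    kx <- paste(sort(X), collapse = ","); ky <- paste(sort(Y), collapse = ",")
    if (length(X) < length(Y)) kx
    else if (length(Y) < length(X)) ky
    else min(kx, ky)
  }

  tb <- tb_new()
  build <- function(G, parent_new) {
    if (length(G) == 1L) {
      tb_add(tb, parent_new, NA_real_, label = G,
             gene = G, species = unname(spmap[G]))
      return(invisible(NULL))
    }
    cand <- candidates(G)
    if (!length(cand))
      stop("no candidate split for gene set {", paste(G, collapse = ","), "}")
    best <- NULL
    for (key in names(cand)) {
      cc <- cand[[key]]
      X <- cc$side; Y <- setdiff(G, X)
      ev <- eval_split(X, Y)
      score <- list(dup = ev$event == "duplication", losses = ev$losses,
                    boot = cc$boot, tk = tiekey(X, Y))
      better <- is.null(best) ||
        (score$dup < best$score$dup) ||
        (score$dup == best$score$dup && score$losses < best$score$losses) ||
        (score$dup == best$score$dup && score$losses == best$score$losses &&
           score$boot > best$score$boot) ||
        (score$dup == best$score$dup && score$losses == best$score$losses &&
           score$boot == best$score$boot && score$tk < best$score$tk)
      if (better) best <- list(cc = cc, X = X, Y = Y, ev = ev, score = score)
    }
    id <- tb_add(tb, parent_new, NA_real_,
                 event = best$ev$event,
                 bootstrap = if (best$score$boot > 0) best$score$boot else NA_real_,
                 supporters = sort(best$cc$supporters))
    build(best$X, id)
    build(best$Y, id)
    invisible(NULL)
  }
  build(genes, 0L)
  merged <- tb_gene_tree(tb)

  # branch lengths: median over input trees of the same rooted clade
  clade_len <- lapply(input_trees, function(t) {
    sets <- clade_genes(t)
    keys <- vapply(sets, split_key, character(1))
    stats::setNames(t$length, keys)
  })
  msets <- clade_genes(merged)
  for (v in seq_along(merged$parent)) {
    key <- split_key(msets[[v]])
    lens <- unlist(lapply(clade_len, function(cl) unname(cl[key])))
    lens <- lens[!is.na(lens)]
    if (length(lens)) merged$length[v] <- stats::median(lens)
  }
  merged$length[merged$root] <- NA_real_

  # reconcile for taxon / dcs annotation (events agree by construction)
  rec <- reconcile(merged, st)
  out <- rec$tree
  out$supporters <- merged$supporters
  out$bootstrap <- merged$bootstrap
  attr(out, "input_ids") <- ids
  attr(out, "lengths") <- "median-of-inputs"
  out
}

#' Per-input-tree branch support summary
#'
#' For each input-tree label, the fraction of final-tree branches it supports
#' and the fraction it supports uniquely, across a collection of merged
#' trees. Denominators count the internal branches of the merged trees in
#' which that input participated.
#'
#' @param final_trees a single merged tree or list of merged trees produced
#'   by [mmerge()].
#' @return a data.frame with columns `tree_id`, `n_branches`, `n_supported`,
#'   `n_unique`, `support_frac`, `unique_frac`.
#' @export
branch_support_summary <- function(final_trees) {
  if (inherits(final_trees, "gene_tree")) final_trees <- list(final_trees)
  all_ids <- sort(unique(unlist(lapply(final_trees, attr, "input_ids"))))
  n_br <- n_sup <- n_unq <- stats::setNames(numeric(length(all_ids)), all_ids)
  for (tr in final_trees) {
    ids <- attr(tr, "input_ids")
    internal <- which(!is_leaf_node(tr))
    n_br[ids] <- n_br[ids] + length(internal)
    for (v in internal) {
      sup <- tr$supporters[[v]]
      if (!length(sup)) next
      n_sup[intersect(sup, ids)] <- n_sup[intersect(sup, ids)] + 1
      if (length(sup) == 1L) n_unq[sup] <- n_unq[sup] + 1
    }
  }
  data.frame(tree_id = all_ids, n_branches = as.integer(n_br),
             n_supported = as.integer(n_sup), n_unique = as.integer(n_unq),
             support_frac = ifelse(n_br > 0, n_sup / n_br, NA_real_),
             unique_frac = ifelse(n_br > 0, n_unq / n_br, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise overlap of branch support between input models
#'
#' For two input-tree labels a and b, overlap = |branches supported by both| /
#' |branches supported by at least one| over all internal branches of the
#' merged trees.
#'
#' @inheritParams branch_support_summary
#' @return a symmetric matrix of overlap fractions.
#' @export
model_overlap <- function(final_trees) {
  if (inherits(final_trees, "gene_tree")) final_trees <- list(final_trees)
  all_ids <- sort(unique(unlist(lapply(final_trees, attr, "input_ids"))))
  k <- length(all_ids)
  both <- matrix(0, k, k, dimnames = list(all_ids, all_ids))
  for (tr in final_trees) {
    for (v in which(!is_leaf_node(tr))) {
      sup <- intersect(tr$supporters[[v]], all_ids)
      if (!length(sup)) next
      both[sup, sup] <- both[sup, sup] + 1
    }
  }
  supported <- diag(both)
  either <- outer(supported, supported, "+") - both
  ifelse(either > 0, both / either, NA_real_)
}
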