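# K tree-score comparison: scale the comparison tree to match the reference
# tree's global divergence as closely as possible (least squares over
# branches paired by leaf bipartition), then report the residual branch
# length distance.

#' K tree score between two trees
#'
#' Branches are paired by identical (unrooted) leaf bipartition, including
#' the terminal branches; a branch present in only one tree is paired with
#' length 0 on the other side. The scale factor
#' `K = sum(b_ref * b_comp) / sum(b_comp^2)` is the least-squares minimiser
#' of `sum((K * b_comp - b_ref)^2)` over all paired branches, and the score
#' is the square root of that minimised sum. Identical trees give K = 1 and
#' score 0; a comparison tree with all lengths scaled by c gives K = 1/c and
#' score 0.
#'
#' @param reference,comparison [gene_tree()]s over the same leaf set, with
#'   branch lengths. Rooted trees are compared on their unrooted bipartition
#'   sets.
#' @return an object of class `tree_comparison`: list with `k_factor`,
#'   `k_score`, `n_matched`, `n_unmatched_ref`, `n_unmatched_comp`.
#' @export
k_score <- function(reference, comparison) {
  lr <- sort(leaf_genes(reference)); lc <- sort(leaf_genes(comparison))
  if (!identical(lr, lc)) stop("trees must share the same leaf set")
  br <- bipartitions(reference, trivial = TRUE)
  bc <- bipartitions(comparison, trivial = TRUE)
  br$length[is.na(br$length)] <- 0
  bc$length[is.na(bc$length)] <- 0
  if (all(bc$length == 0)) stop("comparison tree has no branch lengths (K undefined)")
  keys <- union(br$split, bc$split)
  b_ref <- stats::setNames(rep(0, length(keys)), keys)
  b_comp <- b_ref
  b_ref[br$split] <- br$length
  b_comp[bc$split] <- bc$length
  K <- sum(b_ref * b_comp) / sum(b_comp^2)
  score <- sqrt(sum((K * b_comp - b_ref)^2))
  structure(list(k_factor = K, k_score = score,
                 n_matched = length(intersect(br$split, bc$split)),
                 n_unmatched_ref = length(setdiff(br$split, bc$split)),
                 n_unmatched_comp = length(setdiff(bc$split, br$split))),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat(sprintf("K tree score: %.6g (scale K = %.6g; %d matched, %d/%d unmatched)\n",
              x$k_score, x$k_factor, x$n_matched, x$n_unmatched_ref,
              x$n_unmatched_comp))
  invisible(x)
}

#' Rank candidate trees by similarity to a final tree
#'
#' Computes the K tree score of every input tree against the final merged
#' tree and ranks them ascending (rank 1 = most similar). Ties are broken by
#' label order.
#'
#' @param final the merged reference [gene_tree()].
#' @param inputs named list of [gene_tree()]s.
#' @return data.frame with columns `tree_label`, `k_factor`, `k_score`,
#'   `rank`.
#' @export
rank_trees <- function(final, inputs) {
  stopifnot(length(inputs) >= 1L, !is.null(names(inputs)))
  rows <- lapply(names(inputs), function(lb) {
    ks <- k_score(final, inputs[[lb]])
    data.frame(tree_label = lb, k_factor = ks$k_factor, k_score = ks$k_score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$k_score, out$tree_label), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank-frequency table across families
#'
#' @param rank_tables list of [rank_trees()] results (one per family).
#' @return matrix of counts, labels x ranks.
#' @export
rank_frequency <- function(rank_tables) {
  labels <- sort(unique(unlist(lapply(rank_tables, `[[`, "tree_label"))))
  maxr <- max(vapply(rank_tables, nrow, integer(1)))
  out <- matrix(0L, length(labels), maxr,
                dimnames = list(labels, paste0("rank", seq_len(maxr))))
  for (rt in rank_tables) {
    for (i in seq_len(nrow(rt))) {
      out[rt$tree_label[i], rt$rank[i]] <- out[rt$tree_label[i], rt$rank[i]] + 1L
    }
  }
  out
}
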