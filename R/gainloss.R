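# Birth-death modelling of gene family sizes along an ultrametric species
# tree. Genes are gained and lost independently at a single rate lambda per
# gene per million years; the transition kernel is the equal-rate linear
# birth-death probability
#   P(c | s, t) = sum_j C(s,j) C(s+c-j-1, s-1) a^(s+c-2j) (1-2a)^j,
#   a = lambda*t / (1 + lambda*t),
# with absorbing zero. Family likelihoods are evaluated by the standard
# pruning (post-order dynamic programming) algorithm with ancestral counts
# truncated at n_max, and lambda is estimated by bounded 1-D maximum
# likelihood with iterative exclusion of outlier families.

#' Make a species tree ultrametric from node ages
#'
#' @param species_tree a binary [species_tree()] with labelled internal
#'   nodes.
#' @param node_ages named numeric vector of ages in millions of years, one
#'   per internal node label (leaves default to age 0).
#' @return the species tree with branch lengths `parent age - child age`,
#'   rounded to the nearest integer and floored at 1.
#' @export
make_ultrametric <- function(species_tree, node_ages) {
  st <- species_tree
  if (!is_binary(st)) stop("species tree must be binary (disambiguate multifurcations first)")
  age <- numeric(length(st$parent))
  leaf <- is_leaf_node(st)
  for (v in seq_along(st$parent)) {
    if (leaf[v]) {
      age[v] <- if (st$label[v] %in% names(node_ages)) node_ages[[st$label[v]]] else 0
    } else {
      if (!nzchar(st$label[v]) || !(st$label[v] %in% names(node_ages)))
        stop("no age for internal node '", st$label[v], "'")
      age[v] <- node_ages[[st$label[v]]]
    }
  }
  for (v in seq_along(st$parent)) {
    p <- st$parent[v]
    if (p == 0L) { st$length[v] <- NA_real_; next }
    d <- age[p] - age[v]
    if (d <= 0) stop("non-positive branch implied at '", st$label[v],
                     "' (child age must be smaller than parent age)")
    st$length[v] <- max(1, round(d))
  }
  st
}

#' Birth-death transition probability
#'
#' Probability that a family of `s` genes at the top of a branch of duration
#' `t` leaves `c` genes at the bottom, under the equal-rate birth-death
#' process (rate `lambda` per gene for gain and for loss). Zero is
#' absorbing: `P(c | 0) = [c == 0]`.
#'
#' @param s parent count (>= 0).
#' @param c child count (>= 0).
#' @param t branch duration (millions of years, >= 0).
#' @param lambda rate per gene per million years (> 0).
#' @return a probability.
#' @export
transition_prob <- function(s, c, t, lambda) {
  stopifnot(s >= 0, c >= 0, t >= 0, lambda > 0)
  if (t == 0) return(as.numeric(c == s))
  a <- lambda * t / (1 + lambda * t)
  if (a >= 0.5) stop("lambda * t too large for this parameterization (alpha >= 0.5)")
  if (s == 0) return(as.numeric(c == 0))
  j <- 0:min(s, c)
  terms <- exp(lchoose(s, j) + lchoose(s + c - j - 1, s - 1) +
                 (s + c - 2 * j) * log(a) +
                 j * log1p(-2 * a))
  # j = s = c term has a^0: log(a)*0 is fine even though log(a) finite
  sum(terms)
}

# (n_max+1) x (n_max+1) kernel matrix, rows = parent count 0..n_max;
# vectorized over child counts, summing the j terms row by row
transition_matrix <- function(n_max, t, lambda) {
  M <- matrix(0, n_max + 1L, n_max + 1L)
  M[1L, 1L] <- 1
  if (t == 0) { diag(M) <- 1; return(M) }
  a <- lambda * t / (1 + lambda * t)
  if (a >= 0.5) stop("lambda * t too large for this parameterization (alpha >= 0.5)")
  loga <- log(a); l1m2a <- log1p(-2 * a)
  cs <- 0:n_max
  for (s in seq_len(n_max)) {
    row <- numeric(n_max + 1L)
    for (j in 0:s) {
      ok <- cs >= j
      row[ok] <- row[ok] + exp(lchoose(s, j) +
                                 lchoose(s + cs[ok] - j - 1, s - 1) +
                                 (s + cs[ok] - 2 * j) * loga + j * l1m2a)
    }
    M[s + 1L, ] <- row
  }
  M
}

#' Gain/loss model specification
#'
#' @param species_tree an ultrametric [species_tree()] with branch lengths
#'   in (integer) millions of years.
#' @param lambda gain/loss rate per gene per million years.
#' @param n_max truncation bound on ancestral counts; default
#'   `max(10, 4 * max observed count)` set by the fitting functions.
#' @param root_prior prior over root counts `1..n_max`; default uniform.
#' @return object of class `gainloss_model`.
#' @export
gainloss_model <- function(species_tree, lambda, n_max = 10,
                           root_prior = NULL) {
  stopifnot(lambda > 0, n_max >= 1)
  lens <- species_tree$length
  if (anyNA(lens[-species_tree$root]))
    stop("species tree must have branch lengths on all non-root edges")
  if (is.null(root_prior)) root_prior <- rep(1 / n_max, n_max)
  if (length(root_prior) != n_max) stop("root_prior must have n_max entries")
  structure(list(tree = species_tree, lambda = lambda, n_max = as.integer(n_max),
                 root_prior = root_prior / sum(root_prior)),
            class = "gainloss_model")
}

# per-branch transition matrices (cache by branch duration)
model_matrices <- function(model) {
  st <- model$tree
  out <- vector("list", length(st$parent))
  cache <- list()
  for (v in seq_along(st$parent)) {
    if (st$parent[v] == 0L) next
    key <- format(st$length[v], digits = 12)
    if (is.null(cache[[key]]))
      cache[[key]] <- transition_matrix(model$n_max, st$length[v], model$lambda)
    out[[v]] <- cache[[key]]
  }
  out
}

profile_counts <- function(profile, species) {
  counts <- stats::setNames(rep(0L, length(species)), species)
  hit <- intersect(names(profile), species)
  counts[hit] <- as.integer(profile[hit])
  counts
}

# conditional leaf/subtree likelihood vectors, shared by loglik and the
# ancestral-count DP
family_pruning <- function(counts, model, mats, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  st <- model$tree
  nmax <- model$n_max
  L <- vector("list", length(st$parent))
  back <- vector("list", length(st$parent))  # argmax child count per parent count
  leaf <- is_leaf_node(st)
  for (v in postorder_nodes(st)) {
    if (leaf[v]) {
      vec <- numeric(nmax + 1L)
      vec[counts[[st$label[v]]] + 1L] <- 1
      L[[v]] <- vec
    } else {
      vec <- rep(1, nmax + 1L)
      for (c in st$children[[v]]) {
        M <- mats[[c]]
        if (mode == "sum") {
          vec <- vec * as.numeric(M %*% L[[c]])
        } else {
          prod_mat <- M * rep(L[[c]], each = nmax + 1L)
          best <- max.col(prod_mat, ties.method = "first")  # smallest count on ties
          vec <- vec * prod_mat[cbind(seq_len(nmax + 1L), best)]
          back[[c]] <- best - 1L
        }
      }
      L[[v]] <- vec
    }
  }
  list(L = L, back = back)
}

#' Log-likelihood of a family profile
#'
#' Post-order pruning: the leaf vector is the indicator of the observed
#' count; each internal vector entry `s` multiplies, over children, the
#' probability of reaching the child's vector from count `s`; the
#' log-likelihood sums the root vector against the root prior (over counts
#' `1..n_max`). Species missing from the profile are treated as count 0.
#'
#' @param profile named integer vector of gene counts per species (or a
#'   one-row slice of a profile table).
#' @param model a [gainloss_model()].
#' @return the log-likelihood.
#' @export
family_loglik <- function(profile, model) {
  st <- model$tree
  species <- st$label[is_leaf_node(st)]
  counts <- profile_counts(profile, species)
  if (max(counts) > model$n_max)
    stop("n_max (", model$n_max, ") smaller than the maximum observed count")
  mats <- model_matrices(model)
  pr <- family_pruning(counts, model, mats, mode = "sum")
  rootvec <- pr$L[[st$root]]
  log(sum(model$root_prior * rootvec[-1L]))
}

# fast path: evaluate many profiles at one lambda, batching the pruning over
# families (one (n_max+1) x n_families matrix per tree node)
profiles_loglik <- function(count_matrix, model) {
  mats <- model_matrices(model)
  st <- model$tree
  nmax <- model$n_max
  nf <- nrow(count_matrix)
  leaf <- is_leaf_node(st)
  L <- vector("list", length(st$parent))
  for (v in postorder_nodes(st)) {
    if (leaf[v]) {
      M <- matrix(0, nmax + 1L, nf)
      M[cbind(count_matrix[, st$label[v]] + 1L, seq_len(nf))] <- 1
      L[[v]] <- M
    } else {
      acc <- matrix(1, nmax + 1L, nf)
      for (c in st$children[[v]]) acc <- acc * (mats[[c]] %*% L[[c]])
      L[[v]] <- acc
    }
  }
  ll <- log(colSums(model$root_prior * L[[st$root]][-1L, , drop = FALSE]))
  stats::setNames(ll, rownames(count_matrix))
}

profiles_to_matrix <- function(profiles, species) {
  stopifnot(is.data.frame(profiles), "family_id" %in% names(profiles))
  missing_sp <- setdiff(species, names(profiles))
  m <- matrix(0L, nrow(profiles), length(species),
              dimnames = list(profiles$family_id, species))
  for (s in setdiff(species, missing_sp)) m[, s] <- as.integer(profiles[[s]])
  m
}

#' Keep only families detectable at the species-tree root
#'
#' A family is kept when the species-tree LCA of the species with a positive
#' count is the root, i.e. the family was present in the common ancestor.
#'
#' @param profiles data.frame with a `family_id` column and one count column
#'   per species.
#' @param species_tree the [species_tree()].
#' @return the filtered profiles.
#' @export
root_presence_filter <- function(profiles, species_tree) {
  st <- species_tree
  depth <- st_depths(st)
  sidx <- st_leaf_index(st)
  species <- intersect(names(profiles), names(sidx))
  keep <- vapply(seq_len(nrow(profiles)), function(i) {
    pos <- species[which(unlist(profiles[i, species]) > 0)]
    if (!length(pos)) return(FALSE)
    st_lca(st, depth, unname(sidx[pos])) == st$root
  }, logical(1))
  profiles[keep, , drop = FALSE]
}

#' Estimate the gain/loss rate lambda by maximum likelihood
#'
#' Maximises the summed family log-likelihood over lambda by bounded 1-D
#' search. The search bounds are `[1e-8, b]` with `b` chosen so that
#' `alpha < 0.45` on the longest branch. A fit is accepted only when the
#' maximum is interior to the bounds; otherwise the family with the lowest
#' per-family log-likelihood (an outlier under the boundary lambda) is
#' excluded and the search repeated, up to 20% of the families. The final
#' model scores *all* root-present families at the estimated lambda.
#'
#' @param profiles data.frame of family profiles (`family_id` + one column
#'   per species).
#' @param species_tree an ultrametric [species_tree()].
#' @param n_max count truncation; default `max(10, 4 * max count)`.
#' @param lower lower search bound.
#' @return object of class `gainloss_fit`: list with `lambda`, `loglik`
#'   (total over all root-present families), `family_loglik` (named vector),
#'   `excluded` (family ids dropped during the search), `model`.
#' @export
estimate_lambda <- function(profiles, species_tree, n_max = NULL,
                            lower = 1e-8) {
  st <- species_tree
  species <- st$label[is_leaf_node(st)]
  kept <- root_presence_filter(profiles, st)
  if (!nrow(kept)) stop("no family passes the root-presence filter")
  cm <- profiles_to_matrix(kept, species)
  if (is.null(n_max)) n_max <- max(10L, 4L * max(cm))
  tmax <- max(st$length[-st$root])
  upper <- 0.45 / (0.55 * tmax)  # alpha < 0.45 on the longest branch

  total_ll <- function(lam, rows) {
    model <- gainloss_model(st, lam, n_max)
    profiles_loglik(cm[rows, , drop = FALSE], model)
  }

  active <- seq_len(nrow(cm))
  excluded <- character(0)
  max_excl <- floor(0.2 * nrow(cm))
  repeat {
    opt <- stats::optimize(function(l) sum(total_ll(l, active)),
                           interval = c(lower, upper), maximum = TRUE,
                           tol = 1e-4 * upper)
    lam <- opt$maximum
    span <- upper - lower
    interior <- lam > lower + 0.005 * span && lam < upper - 0.005 * span &&
      opt$objective >= sum(total_ll(lower * 2, active)) &&
      opt$objective >= sum(total_ll(upper * 0.999, active))
    if (interior) break
    if (length(excluded) >= max_excl)
      stop("failed to maximise lambda: no interior maximum after excluding ",
           length(excluded), " families")
    # drop the family scoring worst at the boundary lambda
    ll <- total_ll(lam, active)
    worst <- active[which.min(ll)]
    excluded <- c(excluded, rownames(cm)[worst])
    active <- setdiff(active, worst)
  }

  model <- gainloss_model(st, lam, n_max)
  fam_ll <- profiles_loglik(cm, model)  # all root-present families
  structure(list(lambda = lam, loglik = sum(fam_ll), family_loglik = fam_ll,
                 excluded = excluded, n_families = nrow(cm), model = model),
            class = "gainloss_fit")
}

#' @export
print.gainloss_fit <- function(x, ...) {
  cat(sprintf("gain/loss fit: lambda = %.5g per gene per My (%d families, %d excluded during search)\n",
              x$lambda, x$n_families, length(x$excluded)))
  invisible(x)
}

#' Most-probable ancestral counts and branch expansion/contraction calls
#'
#' Max-product dynamic programming over ancestral counts (ties broken toward
#' the smallest count). Each branch is labelled `expanded` when the child
#' count exceeds the parent count, `contracted` when smaller, else
#' `unchanged`.
#'
#' @param profile named counts per species (one family).
#' @param model a fitted [gainloss_model()].
#' @return list with `counts` (data.frame node/label/count) and `branches`
#'   (data.frame node, parent, change).
#' @export
expansions_contractions <- function(profile, model) {
  st <- model$tree
  species <- st$label[is_leaf_node(st)]
  counts <- profile_counts(profile, species)
  if (max(counts) > model$n_max) stop("n_max smaller than max observed count")
  mats <- model_matrices(model)
  pr <- family_pruning(counts, model, mats, mode = "max")
  nmax <- model$n_max
  assigned <- integer(length(st$parent))
  rootvec <- model$root_prior * pr$L[[st$root]][-1L]
  assigned[st$root] <- which.max(rootvec)  # counts 1..n_max; first = smallest
  for (v in preorder_nodes(st)) {
    if (v == st$root) next
    assigned[v] <- pr$back[[v]][assigned[st$parent[v]] + 1L]
  }
  lab <- st$label
  lab[!nzchar(lab)] <- paste0("node", which(!nzchar(lab)))
  change <- rep(NA_character_, length(assigned))
  for (v in seq_along(assigned)) {
    p <- st$parent[v]
    if (p == 0L) next
    change[v] <- if (assigned[v] > assigned[p]) "expanded"
                 else if (assigned[v] < assigned[p]) "contracted"
                 else "unchanged"
  }
  list(counts = data.frame(node = seq_along(assigned), label = lab,
                           count = assigned, stringsAsFactors = FALSE),
       branches = data.frame(node = which(st$parent != 0L),
                             parent = st$parent[st$parent != 0L],
                             change = change[st$parent != 0L],
                             stringsAsFactors = FALSE))
}

#' Per-branch expansion/contraction totals over many families
#'
#' @param profiles data.frame of family profiles.
#' @param model a fitted [gainloss_model()].
#' @return data.frame per branch: numbers of families expanded, contracted
#'   and unchanged (Fig.-9-style summary).
#' @export
gainloss_summary <- function(profiles, model) {
  st <- model$tree
  species <- st$label[is_leaf_node(st)]
  lab <- st$label
  lab[!nzchar(lab)] <- paste0("node", which(!nzchar(lab)))
  branches <- which(st$parent != 0L)
  expd <- ctr <- unch <- stats::setNames(integer(length(branches)),
                                         lab[branches])
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles_to_matrix(profiles[i, , drop = FALSE], species)[1L, ]
    ec <- expansions_contractions(prof, model)
    ch <- ec$branches$change
    expd <- expd + (ch == "expanded")
    ctr <- ctr + (ch == "contracted")
    unch <- unch + (ch == "unchanged")
  }
  data.frame(branch = names(expd), expanded = as.integer(expd),
             contracted = as.integer(ctr), unchanged = as.integer(unch),
             row.names = NULL, stringsAsFactors = FALSE)
}
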