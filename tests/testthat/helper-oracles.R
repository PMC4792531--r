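# Shared fixtures and independent oracles used across the test files.

# fixed 5-taxon species tree used by the reconciliation sweeps
species5 <- function() {
  parse_newick("(((A:1,B:1)AB:1,C:1)ABC:1,(D:1,E:1)DE:1)Root;",
               type = "species")
}

# gene tree from plain newick plus a species map derived from "x_S" suffixes
gtree_suffix <- function(nw) {
  tr <- parse_newick(nw)
  genes <- leaf_genes(tr)
  set_species(tr, stats::setNames(sub(".*_", "", genes), genes))
}

random_gene_tree <- function(n, species, lengths = TRUE) {
  phy <- ape::rtree(n)
  sp <- sample(species, n, replace = TRUE)
  phy$tip.label <- paste0("g", seq_len(n), "_", sp)
  if (!lengths) phy$edge.length <- NULL
  tr <- from_phylo(phy)
  set_species(tr, stats::setNames(sp, phy$tip.label))
}

# ---- independent brute-force reconciliation oracle --------------------------
# maps nodes by scanning species-tree clade leaf sets, labels duplications by
# overlap of child species clades, and counts losses by explicitly walking
# the species-tree path of every gene-tree edge.
oracle_reconcile <- function(gt, st) {
  sp_sets <- local({
    f <- function(v) {
      if (!length(st$children[[v]])) return(st$label[v])
      sort(unlist(lapply(st$children[[v]], f)))
    }
    lapply(seq_along(st$parent), f)
  })
  smallest_containing <- function(taxa) {
    ok <- which(vapply(sp_sets, function(s) all(taxa %in% s), logical(1)))
    ok[which.min(lengths(sp_sets)[ok])]
  }
  g_spset <- local({
    f <- function(v) {
      if (!length(gt$children[[v]])) return(gt$species[v])
      unique(unlist(lapply(gt$children[[v]], f)))
    }
    lapply(seq_along(gt$parent), f)
  })
  n <- length(gt$parent)
  map <- vapply(seq_len(n),
                function(v) smallest_containing(unique(g_spset[[v]])),
                integer(1))
  ev <- rep(NA_character_, n)
  for (v in seq_len(n)) {
    kids <- gt$children[[v]]
    if (!length(kids)) next
    dup <- FALSE
    for (a in seq_along(kids)) {
      for (b in seq_along(kids)) {
        if (a < b &&
            length(intersect(sp_sets[[map[kids[a]]]], sp_sets[[map[kids[b]]]])))
          dup <- TRUE
      }
    }
    ev[v] <- if (dup) "duplication" else "speciation"
  }
  path_nodes <- function(top, bottom) {
    out <- top; cur <- top
    target <- sp_sets[[bottom]]
    while (cur != bottom) {
      kids <- st$children[[cur]]
      cur <- kids[vapply(kids, function(k) all(target %in% sp_sets[[k]]),
                         logical(1))][1L]
      out <- c(out, cur)
    }
    out
  }
  losses <- numeric(n)
  for (v in seq_len(n)) {
    p <- gt$parent[v]
    if (p == 0L) next
    steps <- length(path_nodes(map[p], map[v])) - 1L
    if (steps > 0L)
      losses[v] <- max(0, steps - 1L + (ev[p] == "duplication"))
  }
  list(events = ev, losses = losses, mapping = map,
       total_dup = sum(ev == "duplication", na.rm = TRUE),
       total_loss = sum(losses))
}

# ---- exhaustive enumeration of rooted binary topologies ---------------------
# nested-list representation: a leaf is a character scalar, an internal node
# a list of two subtrees; trees are built by inserting each new leaf on every
# edge and above the root
insert_leaf_everywhere <- function(t, leaf) {
  res <- list(list(t, leaf))
  if (is.character(t)) return(res)
  for (l in insert_leaf_everywhere(t[[1L]], leaf))
    res <- c(res, list(list(l, t[[2L]])))
  for (r in insert_leaf_everywhere(t[[2L]], leaf))
    res <- c(res, list(list(t[[1L]], r)))
  res
}

enumerate_topologies <- function(labels) {
  trees <- list(labels[[1L]])
  for (lab in labels[-1L])
    trees <- unlist(lapply(trees, insert_leaf_everywhere, leaf = lab),
                    recursive = FALSE)
  trees
}

nested_to_newick <- function(t) {
  if (is.character(t)) return(t)
  paste0("(", nested_to_newick(t[[1L]]), ",", nested_to_newick(t[[2L]]), ")")
}

# ---- independent rooting oracle --------------------------------------------
# enumerates every edge rooting via phytools::reroot on the ape conversion
# and scores each with the brute-force reconciliation oracle
oracle_best_rooting_score <- function(gt, st) {
  phy <- as_phylo(gt)
  phy$edge.length <- rep(1, nrow(phy$edge))
  phy <- ape::unroot(phy)
  sp <- leaf_species(gt)
  scores <- numeric(0)
  for (e in seq_len(nrow(phy$edge))) {
    node <- phy$edge[e, 2L]
    rooted <- phytools::reroot(phy, node.number = node, position = 0.5)
    tr <- set_species(from_phylo(rooted), sp)
    o <- oracle_reconcile(tr, st)
    scores <- c(scores, o$total_dup + o$total_loss)
  }
  min(scores)
}
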