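# Orthologue / paralogue inference from a reconciled gene tree, Fitch-style:
# pairs whose LCA is a speciation are orthologues, same-species pairs under a
# duplication are within-species paralogues. Cross-species pairs under an
# ill-supported duplication (DCS below a threshold) are rescued as
# orthologues when at least one of the genes has no speciation-mediated
# partner in the other species ("no better match"). Orthologues are sub-classified
# one-to-one / one-to-many / many-to-many by the number of co-orthologues in
# each species.

#' Infer orthologue and paralogue pairs from a reconciled tree
#'
#' @param reconciliation a [reconcile()] result (events and DCS set).
#' @param dcs_threshold duplications with DCS strictly below this value are
#'   treated as dubious and may mediate rescued orthologues (default 0.25).
#' @return a data.frame of class `homology_pairs` with columns `gene1`,
#'   `species1`, `gene2`, `species2`, `class` (`ortholog_one2one`,
#'   `ortholog_one2many`, `ortholog_many2many`, `within_species_paralog`),
#'   `node` (mediating tree node), `node_event` (`speciation`,
#'   `duplication`, `dubious_duplication`) and `dcs`. `gene1 < gene2`
#'   lexicographically; each unordered pair appears at most once.
#' @export
infer_homologies <- function(reconciliation, dcs_threshold = 0.25) {
  if (!inherits(reconciliation, "reconciliation"))
    stop("need a reconciled tree (see reconcile())")
  gt <- reconciliation$tree
  leaves <- which(is_leaf_node(gt))
  ng <- length(leaves)
  empty <- data.frame(gene1 = character(0), species1 = character(0),
                      gene2 = character(0), species2 = character(0),
                      class = character(0), node = integer(0),
                      node_event = character(0), dcs = numeric(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("homology_pairs", class(empty))
  if (ng < 2L) return(empty)

  sets <- vector("list", length(gt$parent))  # leaf indices per clade
  for (v in postorder_nodes(gt)) {
    kids <- gt$children[[v]]
    sets[[v]] <- if (length(kids)) unlist(sets[kids], use.names = FALSE) else v
  }

  # LCA of every leaf pair: for each internal node, pairs spanning two
  # different children have that node as LCA
  g1 <- g2 <- integer(0); lca <- integer(0)
  for (v in which(!is_leaf_node(gt))) {
    kids <- gt$children[[v]]
    for (a in seq_along(kids)) {
      for (b in seq_along(kids)) {
        if (a >= b) next
        la <- sets[[kids[a]]]; lb <- sets[[kids[b]]]
        pairs <- expand.grid(la, lb, KEEP.OUT.ATTRS = FALSE)
        g1 <- c(g1, pairs[[1L]]); g2 <- c(g2, pairs[[2L]])
        lca <- c(lca, rep.int(v, nrow(pairs)))
      }
    }
  }

  ev <- gt$event[lca]
  dcs <- gt$dcs[lca]
  sp1 <- gt$species[g1]; sp2 <- gt$species[g2]
  same_sp <- sp1 == sp2
  dubious <- ev == "duplication" & !is.na(dcs) & dcs < dcs_threshold

  # speciation-mediated orthologue degrees: for gene g, how many partners in
  # species S via a speciation LCA
  spec_pair <- !same_sp & ev == "speciation"
  deg_key <- function(g, s) paste(g, s, sep = "\r")
  spec_deg <- table(c(deg_key(g1[spec_pair], sp2[spec_pair]),
                      deg_key(g2[spec_pair], sp1[spec_pair])))
  spec_deg_of <- function(g, s) {
    k <- deg_key(g, s)
    out <- spec_deg[k]
    out[is.na(out)] <- 0L
    as.integer(out)
  }

  # rescue ("no better match"): at least one of the genes has no speciation
  # partner in the other species, so the dubious node is its only route to a
  # counterpart there
  rescued <- !same_sp & dubious &
    (spec_deg_of(g1, sp2) == 0L | spec_deg_of(g2, sp1) == 0L)

  is_orth <- spec_pair | rescued
  is_wsp <- same_sp & ev %in% c("duplication")

  keep <- is_orth | is_wsp
  if (!any(keep)) return(empty)

  g1k <- g1[keep]; g2k <- g2[keep]
  sp1k <- sp1[keep]; sp2k <- sp2[keep]
  orth <- is_orth[keep]

  # orthologue degrees including rescued pairs
  od <- table(c(deg_key(g1k[orth], sp2k[orth]), deg_key(g2k[orth], sp1k[orth])))
  odeg <- function(g, s) {
    out <- od[deg_key(g, s)]
    out[is.na(out)] <- 0L
    as.integer(out)
  }
  d1 <- odeg(g1k, sp2k)  # copies of gene1's co-orthologue set? degree of g1 in sp2
  d2 <- odeg(g2k, sp1k)
  cls <- character(sum(keep))
  cls[!orth] <- "within_species_paralog"
  cls[orth & d1 == 1L & d2 == 1L] <- "ortholog_one2one"
  cls[orth & xor(d1 > 1L, d2 > 1L)] <- "ortholog_one2many"
  cls[orth & d1 > 1L & d2 > 1L] <- "ortholog_many2many"

  node_ev <- ev[keep]
  node_ev[node_ev == "duplication" & dubious[keep]] <- "dubious_duplication"

  out <- data.frame(gene1 = gt$gene[g1k], species1 = sp1k,
                    gene2 = gt$gene[g2k], species2 = sp2k,
                    class = cls, node = lca[keep], node_event = node_ev,
                    dcs = dcs[keep], stringsAsFactors = FALSE)
  # canonical gene order within a pair
  swap <- out$gene1 > out$gene2
  tmp <- out$gene1[swap]; out$gene1[swap] <- out$gene2[swap]; out$gene2[swap] <- tmp
  tmp <- out$species1[swap]; out$species1[swap] <- out$species2[swap]
  out$species2[swap] <- tmp
  out <- out[order(out$gene1, out$gene2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("homology_pairs", class(out))
  out
}

#' Summarise homology pairs per species pair
#'
#' @param pairs a [infer_homologies()] result.
#' @return a list with `counts` (one row per unordered species pair with
#'   counts of each homology class) and `pairs` (the input listing).
#' @export
homology_table <- function(pairs) {
  classes <- c("ortholog_one2one", "ortholog_one2many", "ortholog_many2many",
               "within_species_paralog")
  if (!nrow(pairs)) {
    counts <- data.frame(species1 = character(0), species2 = character(0))
    for (cl in classes) counts[[cl]] <- integer(0)
    return(list(counts = counts, pairs = pairs))
  }
  spa <- pmin(pairs$species1, pairs$species2)
  spb <- pmax(pairs$species1, pairs$species2)
  key <- paste(spa, spb, sep = "\r")
  uk <- sort(unique(key))
  counts <- data.frame(
    species1 = sub("\r.*", "", uk), species2 = sub(".*\r", "", uk),
    stringsAsFactors = FALSE)
  for (cl in classes) {
    counts[[cl]] <- as.integer(table(factor(key[pairs$class == cl],
                                            levels = uk)))
  }
  list(counts = counts, pairs = pairs)
}

# gap between two 1-based inclusive intervals on the same chromosome;
# 0 when they overlap or touch
interval_gap <- function(s1, e1, s2, e2) {
  if (e1 < s2) return(s2 - e1 - 1L)
  if (e2 < s1) return(s1 - e2 - 1L)
  0L
}

#' Synteny-based QC of ncRNA orthology calls
#'
#' A pair of orthologous ncRNAs is *intronic-supported* when both genes lie
#' inside protein-coding host genes and those hosts form a protein orthologue
#' pair of the same orthology class. Pairs without two hosts are
#' *window-supported* when some protein orthologue pair of the same class has
#' one member within `window` bp (upstream or downstream, strand-agnostic)
#' of each ncRNA.
#'
#' @param pairs ncRNA homology pairs ([infer_homologies()] format); only
#'   orthologue classes are assessed.
#' @param annotations data.frame with columns `gene_id`, `species`, `type`
#'   (`ncRNA` / `protein_coding`), `chromosome`, `start`, `end` (1-based
#'   inclusive), `strand`, `host_gene` (NA when not intronic).
#' @param protein_pairs data.frame of protein orthologue pairs with columns
#'   `gene1`, `gene2`, `class`.
#' @param window distance cutoff in bp (default 5000); a protein at a gap of
#'   exactly `window` bp still counts, beyond it does not.
#' @return a list with `pairs` (per-pair `category` = intronic/near,
#'   `supported` flag), `summary` (supported/total and fraction per
#'   category) and `n_skipped` (pairs missing coordinates).
#' @export
synteny_support <- function(pairs, annotations, protein_pairs, window = 5000) {
  orth <- pairs[grepl("^ortholog_", pairs$class), , drop = FALSE]
  ann <- annotations
  rownames(ann) <- NULL
  arow <- function(g, s) {
    i <- which(ann$gene_id == g & ann$species == s)
    if (length(i) != 1L) return(NULL)
    ann[i, , drop = FALSE]
  }
  pkey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  prot_keys <- split(pkey(protein_pairs$gene1, protein_pairs$gene2),
                     protein_pairs$class)
  proteins <- ann[ann$type == "protein_coding", , drop = FALSE]

  n <- nrow(orth)
  category <- character(n); supported <- logical(n); skipped <- logical(n)
  for (i in seq_len(n)) {
    a1 <- arow(orth$gene1[i], orth$species1[i])
    a2 <- arow(orth$gene2[i], orth$species2[i])
    if (is.null(a1) || is.null(a2)) {
      skipped[i] <- TRUE
      next
    }
    cls <- orth$class[i]
    keys <- prot_keys[[cls]]
    if (!is.na(a1$host_gene) && !is.na(a2$host_gene)) {
      category[i] <- "intronic"
      supported[i] <- pkey(a1$host_gene, a2$host_gene) %in% keys
    } else {
      category[i] <- "near"
      # proteins near each ncRNA, in the matching species
      near_of <- function(a) {
        cand <- proteins[proteins$species == a$species &
                           proteins$chromosome == a$chromosome, , drop = FALSE]
        if (!nrow(cand)) return(character(0))
        gaps <- mapply(interval_gap, a$start, a$end, cand$start, cand$end)
        cand$gene_id[gaps <= window]
      }
      n1 <- near_of(a1); n2 <- near_of(a2)
      if (length(n1) && length(n2)) {
        combos <- expand.grid(n1, n2, KEEP.OUT.ATTRS = FALSE,
                              stringsAsFactors = FALSE)
        supported[i] <- any(pkey(combos[[1L]], combos[[2L]]) %in% keys)
      }
    }
  }
  if (any(skipped))
    warning(sum(skipped), " pair(s) skipped: missing coordinates")
  res <- cbind(orth, data.frame(category = category, supported = supported,
                                skipped = skipped, stringsAsFactors = FALSE))
  summ <- do.call(rbind, lapply(c("intronic", "near"), function(cat) {
    sel <- category == cat & !skipped
    data.frame(category = cat, supported = sum(supported[sel]),
               total = sum(sel),
               fraction = if (sum(sel)) sum(supported[sel]) / sum(sel)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(pairs = res, summary = summ, n_skipped = sum(skipped))
}
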