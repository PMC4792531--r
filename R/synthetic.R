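# Synthetic-data generators: gene trees evolved by duplication-loss inside a
# species tree, perturbed candidate trees, birth-death family-size profiles
# and planted synteny fixtures. One global seed drives independent
# per-generator substreams, so adding a generator never changes existing
# fixtures.

#' Simulation configuration
#'
#' @param seed integer master seed; every generator derives its own
#'   substream from it, making all outputs bit-reproducible.
#' @param dup_rate,loss_rate duplication / loss events per gene lineage per
#'   unit of species-tree branch length.
#' @param nni_moves number of random nearest-neighbour interchanges applied
#'   by [perturb_tree()].
#' @param length_noise_sd standard deviation of the log-normal branch length
#'   noise applied by [perturb_tree()].
#' @param n_families number of families for profile / benchmark generation.
#' @param lambda_true birth-death rate used by [simulate_profiles()].
#' @param root_genes gene copies present at the species-tree root.
#' @param retry_limit resampling attempts before giving up on an extinct
#'   family.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, dup_rate = 0.05, loss_rate = 0.02,
                       nni_moves = 1L, length_noise_sd = 0.1,
                       n_families = 50L, lambda_true = 0.002,
                       root_genes = 1L, retry_limit = 100L) {
  stopifnot(dup_rate >= 0, loss_rate >= 0, nni_moves >= 0,
            length_noise_sd >= 0, lambda_true >= 0, root_genes >= 1)
  structure(list(seed = as.integer(seed), dup_rate = dup_rate,
                 loss_rate = loss_rate, nni_moves = as.integer(nni_moves),
                 length_noise_sd = length_noise_sd,
                 n_families = as.integer(n_families),
                 lambda_true = lambda_true, root_genes = as.integer(root_genes),
                 retry_limit = as.integer(retry_limit)),
            class = "sim_config")
}

# deterministic substream: generator id 1 = gene trees, 2 = perturbations,
# 3 = profiles, 4 = synteny; `index` separates families/replicates
substream_seed <- function(seed, generator, index = 0L) {
  set.seed(((abs(as.double(seed)) %% 65536) * 32003 +
              generator * 7919 + index) %% 2147483647)
}

#' Simulate a gene tree by duplication-loss inside a species tree
#'
#' Gene lineages evolve forward in time within the species tree: each
#' lineage duplicates at `dup_rate` and dies at `loss_rate` per unit branch
#' length, and splits into all child lineages at speciations. Extinct
#' lineages are pruned, so surviving duplication nodes (those with
#' descendants in both daughter lineages) are annotated as the ground-truth
#' `"duplication"` events of the returned tree.
#'
#' @param species_tree a [species_tree()] with branch lengths.
#' @param config a [sim_config()].
#' @param family_index index used to derive the family's RNG substream.
#' @return list with `tree` (a [gene_tree()] carrying the true events),
#'   `n_dup` (surviving duplication nodes), `n_loss` (loss events that
#'   occurred), `dup_clades` (list of gene sets under each true duplication).
#' @export
simulate_gene_tree <- function(species_tree, config, family_index = 1L) {
  st <- species_tree
  if (anyNA(st$length[-st$root])) stop("species tree needs branch lengths")
  substream_seed(config$seed, 1L, family_index)
  d <- config$dup_rate; l <- config$loss_rate

  for (attempt in seq_len(config$retry_limit)) {
    counter <- 0L
    n_loss <- 0L
    add_len <- function(node, extra) { node$len <- node$len + extra; node }

    evolve_in_branch <- function(sp, t_rem) {
      # one lineage entering a branch with t_rem time units remaining
      rate <- d + l
      wait <- if (rate > 0) stats::rexp(1L, rate) else Inf
      if (wait < t_rem) {
        if (stats::runif(1L) < l / rate) {
          n_loss <<- n_loss + 1L
          return(NULL)
        }
        left <- evolve_in_branch(sp, t_rem - wait)
        right <- evolve_in_branch(sp, t_rem - wait)
        if (is.null(left) && is.null(right)) return(NULL)
        if (is.null(left)) return(add_len(right, wait))
        if (is.null(right)) return(add_len(left, wait))
        return(list(event = "duplication", len = wait,
                    kids = list(left, right)))
      }
      res <- at_species_node(sp)
      if (is.null(res)) return(NULL)
      add_len(res, t_rem)
    }

    at_species_node <- function(sp) {
      kids_sp <- st$children[[sp]]
      if (!length(kids_sp)) {
        counter <<- counter + 1L
        return(list(gene = paste0("g", counter, "_", st$label[sp]),
                    species = st$label[sp], len = 0, kids = list()))
      }
      subs <- list()
      for (cs in kids_sp) {
        r <- evolve_in_branch(cs, st$length[cs])
        if (!is.null(r)) subs <- c(subs, list(r))
      }
      if (!length(subs)) return(NULL)
      if (length(subs) == 1L) return(subs[[1L]])
      list(event = "speciation", len = 0, kids = subs)
    }

    start_root <- function() {
      lins <- list()
      for (k in seq_len(config$root_genes)) {
        r <- at_species_node(st$root)
        if (!is.null(r)) lins <- c(lins, list(r))
      }
      if (!length(lins)) return(NULL)
      while (length(lins) > 1L) {
        merged <- list(event = "duplication", len = 0,
                       kids = list(lins[[1L]], lins[[2L]]))
        lins <- c(list(merged), lins[-(1:2)])
      }
      lins[[1L]]
    }

    top <- start_root()
    if (!is.null(top)) {
      tb <- tb_new()
      emit <- function(node, parent_new) {
        if (!length(node$kids)) {
          tb_add(tb, parent_new, node$len, label = node$gene,
                 gene = node$gene, species = node$species)
        } else {
          id <- tb_add(tb, parent_new, node$len, event = node$event)
          for (k in node$kids) emit(k, id)
        }
        invisible(NULL)
      }
      emit(top, 0L)
      tree <- tb_gene_tree(tb)
      dup_nodes <- which(!is.na(tree$event) & tree$event == "duplication")
      sets <- clade_genes(tree)
      return(list(tree = tree, n_dup = length(dup_nodes), n_loss = n_loss,
                  dup_clades = lapply(dup_nodes, function(v) sort(sets[[v]]))))
    }
  }
  stop("all lineages went extinct in ", config$retry_limit, " attempts")
}

#' Perturb a gene tree
#'
#' Applies `nni_moves` random nearest-neighbour interchanges, multiplies
#' branch lengths by log-normal noise, and assigns bootstrap values that are
#' high on untouched regions and low around the rearranged edges —
#' a stand-in for the independently inferred candidate trees of a family.
#'
#' @param tree a binary [gene_tree()].
#' @param config a [sim_config()].
#' @param index RNG substream index (one per perturbed copy).
#' @return a [gene_tree()] on the same leaf set.
#' @export
perturb_tree <- function(tree, config, index = 1L) {
  if (config$nni_moves == 0L && config$length_noise_sd == 0) return(tree)
  stopifnot(is_binary(tree))
  substream_seed(config$seed, 2L, index)
  tr <- tree
  touched <- integer(0)
  pick <- function(x) if (length(x) == 1L) x else sample(x, 1L)
  leafness <- function(t) lengths(t$children) == 0L
  for (k in seq_len(config$nni_moves)) {
    leaf <- leafness(tr)
    # candidate v: internal non-root node whose edge to its parent is an
    # internal edge of the *unrooted* tree (the edge between the two root
    # children counts once, and only when the sibling is internal)
    cand <- which(!leaf & tr$parent != 0L)
    cand <- cand[vapply(cand, function(v) {
      u <- tr$parent[v]
      if (u != tr$root) return(TRUE)
      w <- setdiff(tr$children[[u]], v)
      !leaf[w]
    }, logical(1))]
    if (!length(cand)) break
    v <- pick(cand)
    u <- tr$parent[v]
    c <- pick(tr$children[[v]])
    if (u == tr$root) {
      # unrooted edge between the two root children: swap subtrees across it
      w <- setdiff(tr$children[[u]], v)
      s <- pick(tr$children[[w]])
      tr$parent[s] <- v
      tr$parent[c] <- w
      touched <- c(touched, v, w)
    } else {
      s <- pick(setdiff(tr$children[[u]], v))
      tr$parent[s] <- v
      tr$parent[c] <- u
      touched <- c(touched, u, v)
    }
    tr$children <- build_children(tr$parent)
  }
  nl <- length(tr$parent)
  if (config$length_noise_sd > 0) {
    noise <- exp(stats::rnorm(nl, 0, config$length_noise_sd))
    tr$length <- tr$length * noise
  }
  internal <- !is_leaf_node(tr) & tr$parent != 0L
  bs <- rep(95, nl)
  bs[touched] <- 40
  tr$bootstrap[internal] <- bs[internal]
  tr$event <- rep(NA_character_, nl)  # truth labels do not survive inference
  tr
}

#' Simulate birth-death family-size profiles
#'
#' Root counts are drawn uniformly from `1..root_max`; counts then evolve
#' down every branch by exact sampling from the [transition_prob()]
#' distribution.
#'
#' @param species_tree an ultrametric [species_tree()] with branch lengths
#'   in millions of years.
#' @param config a [sim_config()]; `lambda_true` is the simulation rate.
#' @param n_families number of families (default `config$n_families`).
#' @param root_max largest root count.
#' @return list with `profiles` (data.frame `family_id` + per-species
#'   counts) and `ancestral` (matrix of true counts, families x nodes).
#' @export
simulate_profiles <- function(species_tree, config,
                              n_families = config$n_families, root_max = 5L) {
  st <- species_tree
  stopifnot(config$lambda_true > 0)
  substream_seed(config$seed, 3L, 0L)
  lam <- config$lambda_true
  leaf <- is_leaf_node(st)
  species <- st$label[leaf]
  ord <- preorder_nodes(st)

  sample_child <- function(s, t) {
    if (s == 0L) return(0L)
    cap <- 4L * s + 20L
    p <- vapply(0:cap, function(c) transition_prob(s, c, t, lam), numeric(1))
    sample.int(cap + 1L, 1L, prob = p) - 1L
  }

  anc <- matrix(0L, n_families, length(st$parent))
  profs <- matrix(0L, n_families, length(species),
                  dimnames = list(NULL, species))
  for (i in seq_len(n_families)) {
    cnt <- integer(length(st$parent))
    for (v in ord) {
      p <- st$parent[v]
      cnt[v] <- if (p == 0L) sample.int(root_max, 1L)
                else sample_child(cnt[p], st$length[v])
    }
    anc[i, ] <- cnt
    profs[i, ] <- cnt[leaf]
  }
  profiles <- data.frame(family_id = paste0("fam", seq_len(n_families)),
                         profs, stringsAsFactors = FALSE, check.names = FALSE)
  list(profiles = profiles, ancestral = anc)
}

#' Planted synteny fixture for two species
#'
#' Generates coordinate tables, protein orthologue pairs and ncRNA
#' orthologue pairs for two synthetic genomes. A planted fraction of the
#' ncRNA pairs is supported — alternating between intronic placement inside
#' orthologous host genes and placement within 1 kb of orthologous proteins
#' — and the remainder is placed at least 20 kb away from any protein
#' orthologue. Planting is deterministic given the configuration.
#'
#' @param n_pairs number of ncRNA orthologue pairs.
#' @param planted_support_fraction fraction in \[0, 1\] of supported pairs.
#' @param config a [sim_config()] (reserved for seed bookkeeping).
#' @return list with `annotations`, `protein_pairs`, `ncrna_pairs`,
#'   `truth` (logical: pair planted as supported) and `category`.
#' @export
simulate_synteny_fixture <- function(n_pairs, planted_support_fraction,
                                     config = sim_config()) {
  stopifnot(planted_support_fraction >= 0, planted_support_fraction <= 1)
  n_sup <- round(planted_support_fraction * n_pairs)
  rows <- list(); k <- 0L
  add_row <- function(gene_id, species, type, start, end, host = NA_character_) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(gene_id = gene_id, species = species, type = type,
                             chromosome = "1", start = start, end = end,
                             strand = "+", host_gene = host,
                             stringsAsFactors = FALSE)
  }
  truth <- logical(n_pairs); category <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    o <- (i - 1L) * 200000L
    prot <- paste0("prot", i)
    ps <- o + 10000L; pe <- o + 20000L
    for (sp in c("A", "B"))
      add_row(paste0(prot, "_", sp), sp, "protein_coding", ps, pe)
    nc <- paste0("nc", i)
    supported <- i <= n_sup
    truth[i] <- supported
    if (supported && i %% 2L == 1L) {
      category[i] <- "intronic"
      for (sp in c("A", "B"))
        add_row(paste0(nc, "_", sp), sp, "ncRNA", ps + 2000L, ps + 2100L,
                host = paste0(prot, "_", sp))
    } else if (supported) {
      category[i] <- "near"
      for (sp in c("A", "B"))
        add_row(paste0(nc, "_", sp), sp, "ncRNA", pe + 1001L, pe + 1100L)
    } else {
      category[i] <- "far"
      for (sp in c("A", "B"))
        add_row(paste0(nc, "_", sp), sp, "ncRNA", pe + 50000L, pe + 50100L)
    }
  }
  annotations <- do.call(rbind, rows)
  protein_pairs <- data.frame(
    gene1 = paste0("prot", seq_len(n_pairs), "_A"),
    gene2 = paste0("prot", seq_len(n_pairs), "_B"),
    class = "ortholog_one2one", stringsAsFactors = FALSE)
  ncrna_pairs <- data.frame(
    gene1 = paste0("nc", seq_len(n_pairs), "_A"), species1 = "A",
    gene2 = paste0("nc", seq_len(n_pairs), "_B"), species2 = "B",
    class = "ortholog_one2one", stringsAsFactors = FALSE)
  list(annotations = annotations, protein_pairs = protein_pairs,
       ncrna_pairs = ncrna_pairs, truth = truth, category = category)
}
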