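homologies_of <- function(nw, st = example_species_tree(4),
                          dcs_threshold = 0.25) {
  infer_homologies(reconcile(gtree_suffix(nw), st), dcs_threshold)
}

pair_class <- function(pairs, a, b) {
  g1 <- pmin(a, b); g2 <- pmax(a, b)
  hit <- pairs$class[pairs$gene1 == g1 & pairs$gene2 == g2]
  if (length(hit)) hit else NA_character_
}

test_that("homology classes follow the degree rules", {
  # simple speciation: one-to-one
  p1 <- homologies_of("(g1_A,g1_B);")
  expect_equal(pair_class(p1, "g1_A", "g1_B"), "ortholog_one2one")

  # duplication in B after speciation: one-to-many plus a paralogue pair
  p2 <- homologies_of("(g1_A,(g1_B,g2_B));")
  expect_equal(pair_class(p2, "g1_A", "g1_B"), "ortholog_one2many")
  expect_equal(pair_class(p2, "g1_A", "g2_B"), "ortholog_one2many")
  expect_equal(pair_class(p2, "g1_B", "g2_B"), "within_species_paralog")
  expect_equal(nrow(p2), 3L)

  # confident root duplication blocks cross-pairs through it
  p3 <- homologies_of("((g1_A,g1_B),(g2_A,g2_B));")
  expect_equal(pair_class(p3, "g1_A", "g1_B"), "ortholog_one2one")
  expect_equal(pair_class(p3, "g2_A", "g2_B"), "ortholog_one2one")
  expect_equal(pair_class(p3, "g1_A", "g2_A"), "within_species_paralog")
  expect_equal(pair_class(p3, "g1_B", "g2_B"), "within_species_paralog")
  expect_true(is.na(pair_class(p3, "g1_A", "g2_B")))
  expect_equal(nrow(p3), 4L)

  # many-to-many through a deep speciation
  p4 <- homologies_of("((g1_A,g2_A),(g1_B,g2_B));")
  expect_equal(pair_class(p4, "g1_A", "g1_B"), "ortholog_many2many")
  expect_equal(nrow(p4[grepl("many2many", p4$class), ]), 4L)
})

test_that("dubious duplications rescue pairs with no better match", {
  # root duplication with one side missing its B copy; DCS = 1/2 ABC vs ...
  # build a low-DCS duplication: ((A,B),(A)) topology with C on one side
  st <- example_species_tree(4)
  # root dup: left {g1_A, g1_B}, right {g2_A}; DCS = 1/3? species {A,B} vs {A}
  nw <- "((g1_A,g1_B),g2_A);"
  rec <- reconcile(gtree_suffix(nw), st)
  root_dcs <- rec$tree$dcs[rec$tree$root]
  expect_equal(root_dcs, 0.5)  # {A,B} n {A} / {A,B} u {A}

  # with threshold above the DCS, g2_A-g1_B is rescued (no speciation
  # partners for either in the other species)
  p_rescue <- infer_homologies(rec, dcs_threshold = 0.6)
  expect_equal(pair_class(p_rescue, "g2_A", "g1_B"), "ortholog_one2many")
  expect_equal(p_rescue$node_event[p_rescue$gene1 == "g1_B" &
                                     p_rescue$gene2 == "g2_A"],
               "dubious_duplication")
  # g1_A has a speciation partner in B, so g1_A-g1_B stays and the rescued
  # pair makes B's gene one2many
  expect_equal(pair_class(p_rescue, "g1_A", "g1_B"), "ortholog_one2many")

  # below the threshold nothing is rescued
  p_norescue <- infer_homologies(rec, dcs_threshold = 0.25)
  expect_true(is.na(pair_class(p_norescue, "g2_A", "g1_B")))

  # disabling the rescue never increases the orthologue count
  set.seed(61)
  st8 <- example_species_tree(8)
  for (i in 1:20) {
    cfg <- sim_config(seed = 600 + i, dup_rate = 0.15, loss_rate = 0.1)
    sim <- simulate_gene_tree(st8, cfg, i)
    if (n_leaves(sim$tree) < 3) next
    rec <- reconcile(sim$tree, st8)
    with_rescue <- infer_homologies(rec, dcs_threshold = 0.25)
    without <- infer_homologies(rec, dcs_threshold = 0)
    n_orth <- function(p) sum(grepl("^ortholog_", p$class))
    expect_lte(n_orth(without), n_orth(with_rescue))
  }
})

test_that("one2one orthology is a partial matching per species pair", {
  set.seed(62)
  st <- example_species_tree(6)
  for (i in 1:25) {
    cfg <- sim_config(seed = 700 + i, dup_rate = 0.15, loss_rate = 0.08)
    sim <- simulate_gene_tree(st, cfg, i)
    if (n_leaves(sim$tree) < 3) next
    pairs <- infer_homologies(reconcile(sim$tree, st))
    o11 <- pairs[pairs$class == "ortholog_one2one", , drop = FALSE]
    if (!nrow(o11)) next
    # no gene appears twice against the same partner species
    k1 <- paste(o11$gene1, o11$species2)
    k2 <- paste(o11$gene2, o11$species1)
    expect_false(anyDuplicated(k1) > 0)
    expect_false(anyDuplicated(k2) > 0)
    # every cross-species speciation pair lands in exactly one class
    orth <- pairs[grepl("^ortholog_", pairs$class), , drop = FALSE]
    expect_false(anyDuplicated(paste(orth$gene1, orth$gene2)) > 0)
  }
})

test_that("homology_table counts per species pair", {
  p <- homologies_of("((g1_A,g1_B),g1_C);", example_species_tree(4))
  tab <- homology_table(p)
  expect_equal(nrow(tab$counts), 3L)
  expect_equal(sum(tab$counts$ortholog_one2one), 3L)
  expect_equal(sum(tab$counts$ortholog_one2many), 0L)

  empty <- homology_table(p[0, , drop = FALSE])
  expect_equal(nrow(empty$counts), 0L)
  expect_true("ortholog_one2one" %in% names(empty$counts))
})

test_that("synteny support distinguishes intronic, near and unsupported pairs", {
  fx <- simulate_synteny_fixture(20, 0.75)
  res <- synteny_support(fx$ncrna_pairs, fx$annotations, fx$protein_pairs)
  expect_equal(sum(res$summary$supported) / sum(res$summary$total), 0.75)
  expect_equal(res$summary$fraction[res$summary$category == "intronic"], 1)

  # all or nothing
  expect_equal(with(synteny_support(simulate_synteny_fixture(10, 1)$ncrna_pairs,
                                    simulate_synteny_fixture(10, 1)$annotations,
                                    simulate_synteny_fixture(10, 1)$protein_pairs)$summary,
                    sum(supported) / sum(total)), 1)
  fx0 <- simulate_synteny_fixture(10, 0)
  res0 <- synteny_support(fx0$ncrna_pairs, fx0$annotations, fx0$protein_pairs)
  expect_equal(sum(res0$summary$supported), 0L)

  # window boundary: gap of exactly `window` counts, one more bp does not
  ann <- data.frame(
    gene_id = c("p_A", "p_B", "n_A", "n_B"),
    species = c("A", "B", "A", "B"),
    type = c("protein_coding", "protein_coding", "ncRNA", "ncRNA"),
    chromosome = "1",
    start = c(1000L, 1000L, 7001L, 7001L),
    end = c(2000L, 2000L, 7100L, 7100L),
    strand = "+", host_gene = NA_character_, stringsAsFactors = FALSE)
  prot <- data.frame(gene1 = "p_A", gene2 = "p_B",
                     class = "ortholog_one2one", stringsAsFactors = FALSE)
  ncp <- data.frame(gene1 = "n_A", species1 = "A", gene2 = "n_B",
                    species2 = "B", class = "ortholog_one2one",
                    stringsAsFactors = FALSE)
  at_gap <- function(gap) {
    a <- ann; a$start[3:4] <- 2000L + gap + 1L; a$end[3:4] <- a$start[3:4] + 99L
    synteny_support(ncp, a, prot, window = 5000)$pairs$supported
  }
  expect_true(at_gap(5000L))
  expect_false(at_gap(5001L))

  # class mismatch between ncRNA and protein pair blocks support
  prot2 <- prot; prot2$class <- "ortholog_one2many"
  expect_false(synteny_support(ncp, ann, prot2)$pairs$supported)

  # missing coordinates are skipped with a warning
  expect_warning(res_skip <- synteny_support(ncp, ann[-3L, ], prot),
                 "skipped")
  expect_equal(res_skip$n_skipped, 1L)
})
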