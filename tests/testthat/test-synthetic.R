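test_that("gene-tree simulation respects the configured rates and seed", {
  st <- example_species_tree(8)

  # no events: one gene per species, congruent with the species tree
  s0 <- simulate_gene_tree(st, sim_config(seed = 1, dup_rate = 0,
                                          loss_rate = 0), 1)
  expect_equal(n_leaves(s0$tree), 8L)
  expect_setequal(unname(leaf_species(s0$tree)), LETTERS[1:8])
  r0 <- reconcile(s0$tree, st)
  expect_equal(r0$total_dup, 0)
  expect_equal(r0$total_loss, 0)
  expect_equal(s0$n_dup, 0L)

  # a forced root duplication doubles every species
  s2 <- simulate_gene_tree(st, sim_config(seed = 1, dup_rate = 0,
                                          loss_rate = 0, root_genes = 2), 1)
  expect_true(all(table(leaf_species(s2$tree)) == 2))
  expect_equal(s2$n_dup, 1L)

  # bit-reproducible under a fixed seed; different indices differ
  cfg <- sim_config(seed = 33)
  a <- simulate_gene_tree(st, cfg, 5)
  b <- simulate_gene_tree(st, cfg, 5)
  expect_identical(write_newick(a$tree), write_newick(b$tree))
  c <- simulate_gene_tree(st, cfg, 6)
  expect_false(identical(write_newick(a$tree), write_newick(c$tree)))
})

test_that("reconciliation recovers most simulated duplication nodes at low rates", {
  st <- example_species_tree(8)
  found <- total <- 0L
  for (i in 1:200) {
    sim <- simulate_gene_tree(st, sim_config(seed = 1000 + i, dup_rate = 0.04,
                                             loss_rate = 0.015), i)
    if (!sim$n_dup) next
    rec <- reconcile(sim$tree, st)
    sets <- clade_genes(rec$tree)
    rec_dup_clades <- lapply(which(rec$events == "duplication"),
                             function(v) sort(sets[[v]]))
    for (cl in sim$dup_clades) {
      total <- total + 1L
      if (any(vapply(rec_dup_clades, identical, logical(1), cl)))
        found <- found + 1L
    }
  }
  expect_gt(total, 50L)
  expect_gte(found / total, 0.95)
})

test_that("perturb_tree explores the NNI neighbourhood and keeps the leaf set", {
  tr <- gtree_suffix("((g1_A:1,g1_B:1):1,(g1_C:1,g1_D:1):1);")

  # zero moves and zero noise: identical
  same <- perturb_tree(tr, sim_config(seed = 1, nni_moves = 0,
                                      length_noise_sd = 0))
  expect_identical(write_newick(same), write_newick(tr))

  # one NNI on a 4-leaf tree yields one of the two alternative topologies
  seen <- character(0)
  for (i in 1:20) {
    p <- perturb_tree(tr, sim_config(seed = i, nni_moves = 1,
                                     length_noise_sd = 0), i)
    expect_setequal(leaf_genes(p), leaf_genes(tr))
    sp <- bipartitions(p)$split
    expect_false(identical(sp, bipartitions(tr)$split))
    seen <- union(seen, sp)
  }
  expect_setequal(seen, c("g1_B|g1_C", "g1_B|g1_D"))

  # perturbed copies carry bootstraps, lower near the rearranged edges
  p <- perturb_tree(gtree_suffix("(((g1_A,g1_B),(g1_C,g1_D)),((g1_E,g1_F),(g1_G,g1_H)));"),
                    sim_config(seed = 4, nni_moves = 1, length_noise_sd = 0.1))
  bs <- p$bootstrap[!is.na(p$bootstrap)]
  expect_true(any(bs == 40) && any(bs == 95))
})

test_that("profile simulation matches the transition kernel empirically", {
  # single branch: empirical child-count frequencies vs kernel within 3 SE
  st1 <- parse_newick("(A:50)Root;", type = "species")
  sim <- simulate_profiles(st1, sim_config(seed = 13, lambda_true = 0.004,
                                           n_families = 20000), root_max = 1L)
  counts <- sim$profiles$A
  for (c in 0:3) {
    p_hat <- mean(counts == c)
    p_true <- transition_prob(1, c, 50, 0.004)
    se <- sqrt(p_true * (1 - p_true) / length(counts))
    expect_lt(abs(p_hat - p_true), 3 * se + 1e-12)
  }

  # lambda -> 0: leaf counts equal the root count
  st2 <- parse_newick("((A:10,B:10)AB:20,C:30)Root;", type = "species")
  s0 <- simulate_profiles(st2, sim_config(seed = 3, lambda_true = 1e-9,
                                          n_families = 50))
  root_idx <- st2$root
  expect_true(all(s0$profiles$A == s0$ancestral[, root_idx]))
  expect_true(all(s0$profiles$A == s0$profiles$B &
                    s0$profiles$B == s0$profiles$C))

  # reproducibility
  s1 <- simulate_profiles(st2, sim_config(seed = 5, n_families = 10))
  s2 <- simulate_profiles(st2, sim_config(seed = 5, n_families = 10))
  expect_identical(s1$profiles, s2$profiles)
})

test_that("synteny fixtures plant the requested support exactly", {
  for (f in c(0, 0.5, 1)) {
    fx <- simulate_synteny_fixture(40, f)
    res <- synteny_support(fx$ncrna_pairs, fx$annotations, fx$protein_pairs)
    expect_equal(sum(res$summary$supported) / sum(res$summary$total), f)
  }
  fx <- simulate_synteny_fixture(200, 0.75)
  res <- synteny_support(fx$ncrna_pairs, fx$annotations, fx$protein_pairs)
  expect_equal(sum(res$summary$supported) / sum(res$summary$total), 0.75)
  expect_equal(res$pairs$supported, fx$truth)
})
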