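test_that("p-distance matrix matches hand counts and handles gaps", {
  aln <- c(s1 = "ACGT", s2 = "ACGA", s3 = "ACGT")
  d <- distance_matrix(aln)
  expect_equal(d["s1", "s2"], 0.25)
  expect_equal(d["s1", "s3"], 0)
  expect_equal(diag(d), c(s1 = 0, s2 = 0, s3 = 0))
  expect_equal(d, t(d))

  # gapped columns excluded; all-gap overlap gets the matrix maximum
  aln2 <- c(a = "AC--", b = "AT--", c = "--GG")
  d2 <- distance_matrix(aln2)
  expect_equal(d2["a", "b"], 0.5)
  expect_equal(d2["a", "c"], max(d2))

  expect_error(distance_matrix(c(a = "ACGT", b = "ACG")), "ragged")

  set.seed(9)
  rnd <- vapply(1:6, function(i)
    paste(sample(c("A", "C", "G", "U", "-"), 30, TRUE), collapse = ""),
    character(1))
  names(rnd) <- paste0("g", 1:6)
  d3 <- distance_matrix(rnd)
  expect_equal(d3, t(d3))
  expect_true(all(diag(d3) == 0))
})

test_that("neighbour joining solves the 3-taxon case and recovers additive trees", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  lens <- stats::setNames(tr$length[is_leaf_node(tr)], leaf_genes(tr))
  expect_equal(lens[c("a", "b", "c")], c(a = 1, b = 1, c = 3))

  # additive 5-taxon matrix: NJ recovers the generating topology exactly
  gen <- ape::read.tree(text = "((a:1,b:2):1,(c:1,d:2):2,e:3);")
  rec <- neighbor_joining(cophenetic(gen))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(as_phylo(rec)), gen)), 0)

  # degenerate all-equal distances: valid deterministic output
  deq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  t1 <- neighbor_joining(deq)
  t2 <- neighbor_joining(deq)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_true(all(t1$length[!is.na(t1$length)] >= 0))

  bad <- d; bad[1, 2] <- 9
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("split_family cuts the guide tree into bounded clusters", {
  # small family: single cluster
  genes <- paste0("g", 1:5)
  phy <- ape::rtree(5); phy$tip.label <- genes
  guide <- from_phylo(phy)
  h <- split_family(genes, guide, max_size = 400)
  expect_equal(hierarchy_clusters(h), list(cluster1 = sort(genes)))

  # balanced 8-leaf tree with max_size 2 yields the 4 cherries
  nw <- "(((a:1,b:1):2,(c:1,d:1):2):1,((e:1,f:1):2,(g:1,h:1):2):1);"
  guide8 <- parse_newick(nw)
  h8 <- split_family(letters[1:8], guide8, max_size = 2)
  cl <- hierarchy_clusters(h8)
  expect_setequal(vapply(cl, paste, character(1), collapse = ""),
                  c("ab", "cd", "ef", "gh"))

  # random big trees: clusters partition the leaves, all within bound
  set.seed(21)
  phy <- ape::rtree(300)
  phy$tip.label <- sprintf("g%03d", 1:300)
  guide <- from_phylo(phy)
  h3 <- split_family(phy$tip.label, guide, max_size = 40)
  cl3 <- hierarchy_clusters(h3)
  expect_true(all(lengths(cl3) <= 40))
  expect_setequal(unlist(cl3), phy$tip.label)
  expect_equal(sum(lengths(cl3)), 300L)

  expect_error(split_family(genes, guide, max_size = 0), "max_size")
})

test_that("assemble_supertree grafts each subtree intact", {
  # two cherry clusters
  guide <- parse_newick("((a1:1,a2:1):3,(b1:1,b2:1):3);")
  h <- split_family(c("a1", "a2", "b1", "b2"), guide, max_size = 2)
  cl0 <- hierarchy_clusters(h)
  subs <- lapply(cl0, function(g) restrict(guide, g))
  sup <- assemble_supertree(h, subs)
  expect_setequal(bipartitions(sup)$split, c("b1|b2"))
  expect_equal(n_leaves(sup), 4L)

  # single cluster: the subtree itself
  cherry <- parse_newick("(a1:1,a2:1);")
  h1 <- split_family(c("a1", "a2"), cherry, max_size = 10)
  expect_identical(write_newick(assemble_supertree(h1, list(cherry))),
                   write_newick(cherry))

  expect_error(assemble_supertree(h, list(cluster1 = subs[[1L]],
                                          cluster2 = subs[[1L]])),
               "does not match")

  # property: cutting a tree and reassembling its own clades preserves all
  # cut bipartitions and every subtree appears as an intact clade
  set.seed(31)
  for (i in 1:10) {
    phy <- ape::rtree(40); phy$tip.label <- sprintf("g%02d", 1:40)
    tr <- from_phylo(phy)
    h <- split_family(leaf_genes(tr), tr, max_size = 12)
    cl <- hierarchy_clusters(h)
    subs <- lapply(cl, function(g) restrict(tr, g))
    sup <- assemble_supertree(h, subs)
    expect_setequal(leaf_genes(sup), leaf_genes(tr))
    sup_splits <- bipartitions(sup, trivial = TRUE)$split
    for (g in cl[lengths(cl) >= 2]) {
      sub_splits <- bipartitions(restrict(sup, g), trivial = TRUE)$split
      orig_splits <- bipartitions(restrict(tr, g), trivial = TRUE)$split
      expect_setequal(sub_splits, orig_splits)
    }
  }
})

test_that("fast-mode trigger is strict at 150 kb", {
  expect_false(needs_fast_mode(150000))
  expect_true(needs_fast_mode(150001))
  expect_false(needs_fast_mode(0))
  expect_error(needs_fast_mode(-1))
})
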