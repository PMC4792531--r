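# 6-species ultrametric tree used across the gain/loss tests
ultra6 <- function() {
  parse_newick(paste0("(((Hsap:9,Ptro:9)Homininae:34,Cjac:43)Primates:49,",
                      "(Mmus:80,Tgut:80)Other:12)Root;"), type = "species")
}

test_that("make_ultrametric subtracts ages, rounds and validates", {
  st <- parse_newick("((A,B)AB,C)Root;", type = "species")
  u <- make_ultrametric(st, c(Root = 100, AB = 60))
  expect_equal(sort(u$length[-u$root]), c(40, 60, 60, 100))
  # leaf branch = parent age - 0
  expect_equal(u$length[which(u$label == "C")], 100)

  expect_error(make_ultrametric(st, c(Root = 60, AB = 60)), "non-positive")

  # random ages: pre-rounding path sums from the root are equal (all ages 0
  # at the leaves), so rounded path sums differ by at most the rounding
  set.seed(81)
  for (i in 1:20) {
    ages <- c(Root = 100, AB = runif(1, 1, 99))
    u <- make_ultrametric(st, ages)
    depths <- c(u$length[which(u$label == "A")] +
                  u$length[which(u$label == "AB")],
                u$length[which(u$label == "C")])
    expect_lt(abs(depths[1] - depths[2]), 1.5)
  }
  # sub-unit implied branches are floored at 1
  u2 <- make_ultrametric(st, c(Root = 100, AB = 99.8))
  expect_equal(u2$length[which(u2$label == "AB")], 1)
})

test_that("transition kernel matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  lambda <- 0.002
  for (t in c(9, 43, 80)) {
    N <- 60
    Q <- matrix(0, N + 1, N + 1)
    for (s in 1:N) {
      Q[s + 1, s] <- s * lambda
      if (s < N) Q[s + 1, s + 2] <- s * lambda
      Q[s + 1, s + 1] <- -2 * s * lambda
    }
    P <- as.matrix(Matrix::expm(Q * t))
    for (s in 1:5) {
      for (c in 0:5) {
        expect_lt(abs(transition_prob(s, c, t, lambda) - P[s + 1, c + 1]),
                  1e-6)
      }
    }
  }
  # identity kernel at t = 0; alpha closed form for extinction from 1 copy
  expect_equal(transition_prob(3, 3, 0, 0.01), 1)
  expect_equal(transition_prob(3, 2, 0, 0.01), 0)
  t <- 40; lambda <- 0.002
  expect_equal(transition_prob(1, 0, t, lambda),
               lambda * t / (1 + lambda * t))
  expect_error(transition_prob(2, 2, 1000, 0.01), "alpha")

  # rows nearly sum to one at a generous truncation
  for (s in 1:5) {
    tot <- sum(vapply(0:50, function(c) transition_prob(s, c, 80, 0.004),
                      numeric(1)))
    expect_gt(tot, 1 - 1e-6)
  }
})

test_that("pruning likelihood equals exhaustive enumeration and is truncation-stable", {
  st <- parse_newick("((A:10,B:10)AB:20,C:30)Root;", type = "species")
  lambda <- 0.005; nmax <- 6
  model <- gainloss_model(st, lambda, n_max = nmax)
  counts <- c(A = 1L, B = 2L, C = 1L)
  ll <- family_loglik(counts, model)
  brute <- 0
  for (s in 1:nmax) {
    for (m in 0:nmax) {
      brute <- brute + (1 / nmax) *
        transition_prob(s, m, 20, lambda) *
        transition_prob(m, 1, 10, lambda) *
        transition_prob(m, 2, 10, lambda) *
        transition_prob(s, 1, 30, lambda)
    }
  }
  expect_equal(ll, log(brute), tolerance = 1e-12)

  # missing species count as zero
  expect_equal(family_loglik(c(A = 1L, B = 2L), model),
               family_loglik(c(A = 1L, B = 2L, C = 0L), model))
  expect_error(family_loglik(c(A = 9L, B = 1L, C = 1L), model), "n_max")

  # truncation stability: growing n_max beyond 4x the max count changes
  # almost nothing (priors matched on the common support)
  ll1 <- family_loglik(counts, gainloss_model(st, lambda, n_max = 8,
                                              root_prior = c(rep(1, 4), rep(0, 4))))
  ll2 <- family_loglik(counts, gainloss_model(st, lambda, n_max = 16,
                                              root_prior = c(rep(1, 4), rep(0, 12))))
  expect_lt(abs(ll1 - ll2), 1e-8)

  # likelihood of a (1,1) profile tends to certainty as lambda -> 0 with a
  # point-mass root prior
  st2 <- parse_newick("(A:10,B:10)Root;", type = "species")
  m2 <- gainloss_model(st2, 1e-7, n_max = 4, root_prior = c(1, 0, 0, 0))
  expect_gt(exp(family_loglik(c(A = 1L, B = 1L), m2)), 1 - 1e-5)
})

test_that("root-presence filter keeps families spanning the root", {
  st <- ultra6()
  profiles <- data.frame(
    family_id = c("span", "primates_only", "one_leaf", "empty"),
    Hsap = c(1L, 2L, 0L, 0L), Ptro = c(0L, 1L, 0L, 0L),
    Cjac = c(0L, 1L, 0L, 0L), Mmus = c(2L, 0L, 3L, 0L),
    Tgut = c(0L, 0L, 0L, 0L), stringsAsFactors = FALSE)
  kept <- root_presence_filter(profiles, st)
  expect_equal(kept$family_id, "span")

  # random profiles agree with a direct clade check
  set.seed(82)
  species <- c("Hsap", "Ptro", "Cjac", "Mmus", "Tgut")
  left <- c("Hsap", "Ptro", "Cjac")  # primates clade under the root
  for (i in 1:50) {
    cnt <- stats::rpois(5, 0.7)
    prof <- data.frame(family_id = "f", t(stats::setNames(cnt, species)))
    pos <- species[cnt > 0]
    expected <- length(pos) > 0 &&
      !(all(pos %in% left) || all(pos %in% setdiff(species, left)))
    expect_equal(nrow(root_presence_filter(prof, st)) == 1L, expected)
  }
})

test_that("lambda estimation recovers the simulated rate and excludes planted outliers", {
  st <- ultra6()
  cfg <- sim_config(seed = 42, lambda_true = 0.002, n_families = 300)
  sim <- simulate_profiles(st, cfg)
  kept <- root_presence_filter(sim$profiles, st)
  expect_gt(nrow(kept), 100)
  fit <- estimate_lambda(sim$profiles, st)
  expect_lt(abs(fit$lambda - 0.002) / 0.002, 0.2)
  expect_equal(length(fit$family_loglik), nrow(kept))

  # a family with absurd counts has the lowest likelihood under the fit
  outlier <- kept[1, ]
  outlier$family_id <- "outlier"
  outlier[, c("Hsap", "Ptro", "Cjac", "Mmus", "Tgut")] <-
    c(25L, 1L, 1L, 25L, 1L)
  withal <- rbind(kept, outlier)
  fit2 <- estimate_lambda(withal, st)
  expect_equal(names(which.min(fit2$family_loglik)), "outlier")
})

test_that("ancestral count DP labels expansions and contractions", {
  st <- parse_newick("((A:10,B:10)AB:20,C:30)Root;", type = "species")
  model <- gainloss_model(st, 0.003, n_max = 16)

  # identical counts everywhere: all branches unchanged
  ec <- expansions_contractions(c(A = 2L, B = 2L, C = 2L), model)
  expect_true(all(ec$branches$change == "unchanged"))
  expect_true(all(ec$counts$count == 2L))

  # counts (4,4,1): branch to the 1-count leaf contracted
  ec2 <- expansions_contractions(c(A = 4L, B = 4L, C = 1L), model)
  leafC <- which(ec2$counts$label == "C")
  expect_equal(ec2$branches$change[ec2$branches$node == leafC], "contracted")
  ab <- which(ec2$counts$label == "AB")
  expect_equal(ec2$counts$count[ab], 4L)

  # aggregation equals a recount of the individual labels
  cfg <- sim_config(seed = 9, lambda_true = 0.004, n_families = 25)
  sim <- simulate_profiles(parse_newick("((A:50,B:50)AB:50,C:100)Root;",
                                        type = "species"), cfg)
  model2 <- gainloss_model(parse_newick("((A:50,B:50)AB:50,C:100)Root;",
                                        type = "species"), 0.004, n_max = 40)
  summ <- gainloss_summary(sim$profiles, model2)
  manual <- c(expanded = 0L, contracted = 0L)
  for (i in seq_len(nrow(sim$profiles))) {
    prof <- unlist(sim$profiles[i, c("A", "B", "C")])
    ch <- expansions_contractions(prof, model2)$branches$change
    manual["expanded"] <- manual["expanded"] + sum(ch == "expanded")
    manual["contracted"] <- manual["contracted"] + sum(ch == "contracted")
  }
  expect_equal(sum(summ$expanded), unname(manual["expanded"]))
  expect_equal(sum(summ$contracted), unname(manual["contracted"]))
})
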