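tree3 <- read_newick("(A:0.4,(B:0.25,C:0.25):0.15);")

test_that("root-presence parsimony matches brute-force assignment enumeration", {
  tr10 <- ape::read.tree(text = "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,((G:1,H:1):1,(I:1,J:1):1):1):1);")
  all_present <- matrix(1L, 1, 10, dimnames = list("f", tr10$tip.label))
  expect_equal(parsimony_root_presence(all_present, tr10), "f")
  one_leaf <- all_present; one_leaf[1, ] <- 0L; one_leaf[1, "A"] <- 1L
  expect_equal(length(parsimony_root_presence(one_leaf, tr10)), 0L)

  # brute force: minimise changes over all internal-node assignments on 6-leaf trees
  brute_root_present <- function(pattern, tree) {
    tr <- stats::reorder(tree, "postorder")
    ntip <- ape::Ntip(tr)
    nint <- tr$Nnode
    best_cost <- Inf; root_can_present <- FALSE
    for (mask in 0:(2^nint - 1)) {
      states <- c(pattern[tr$tip.label] > 0,
                  as.logical(bitwAnd(2^(0:(nint - 1)), mask)))
      cost <- sum(states[tr$edge[, 1]] != states[tr$edge[, 2]])
      if (cost < best_cost) {
        best_cost <- cost
        root_can_present <- states[ntip + 1]
      } else if (cost == best_cost && states[ntip + 1]) {
        root_can_present <- TRUE
      }
    }
    unname(root_can_present)
  }
  set.seed(17)
  tr6 <- ape::rtree(6)
  for (rep in 1:20) {
    pat <- stats::setNames(rbinom(6, 1, 0.5), tr6$tip.label)
    if (sum(pat) == 0) next
    m <- matrix(as.integer(pat), 1, 6, dimnames = list("f", names(pat)))
    got <- length(parsimony_root_presence(m, tr6)) == 1L
    expect_equal(got, brute_root_present(pat, tr6), info = paste(pat, collapse = ""))
  }
})

test_that("copy-range filter keeps range exactly at the bound", {
  m <- rbind(f1 = c(A = 250L, B = 10L, C = 10L),
             f2 = c(A = 210L, B = 10L, C = 10L),
             f3 = c(A = 5L, B = 3L, C = 1L))
  expect_equal(filter_copy_range(m), c("f2", "f3"))
  expect_equal(filter_copy_range(m, max_range = 4), "f3")
})

test_that("transition probabilities are a valid kernel with the right limits", {
  expect_equal(bd_transition_prob(5, 5, 1e-9, 0.01), 1, tolerance = 1e-6)
  expect_equal(bd_transition_prob(0, 0, 1, 0.5), 1)
  expect_equal(bd_transition_prob(0, 3, 1, 0.5), 0)
  for (s in c(1, 3, 7, 20)) {
    row <- bd_transition_prob(s, 0:200, 1, 0.4)
    expect_true(all(row >= 0 & row <= 1))
    expect_equal(sum(row), 1, tolerance = 1e-8)
  }
})

test_that("transition rows match the truncated matrix-exponential oracle", {
  n_states <- 101L
  oracle_row <- function(s, t, lambda) {
    # generator of the linear birth-death chain on 0..100
    Q <- matrix(0, n_states, n_states)
    for (n in 1:(n_states - 1L)) {
      k <- n - 1L  # state value
      if (k > 0) {
        Q[n, n - 1L] <- lambda * k
        Q[n, n + 1L] <- lambda * k
        Q[n, n] <- -2 * lambda * k
      }
    }
    k <- n_states - 1L
    Q[n_states, n_states - 1L] <- lambda * k
    Q[n_states, n_states] <- -lambda * k   # truncation boundary
    P <- Matrix::expm(Matrix::Matrix(Q * t, sparse = TRUE))
    as.numeric(P[s + 1L, ])
  }
  for (cfg in list(c(s = 3, t = 0.2, lam = 1), c(s = 1, t = 0.5, lam = 0.6),
                   c(s = 8, t = 0.1, lam = 2))) {
    got <- bd_transition_prob(cfg[["s"]], 0:40, cfg[["t"]], cfg[["lam"]])
    want <- oracle_row(cfg[["s"]], cfg[["t"]], cfg[["lam"]])[1:41]
    expect_equal(got, want, tolerance = 1e-8)
  }
})

test_that("pruning likelihood equals exhaustive summation on small trees", {
  s_max <- 8L; root_max <- 5L
  model <- bd_model(edge_partition(tree3), c(background = 0.8))
  counts <- c(A = 2L, B = 1L, C = 3L)
  got <- family_loglik(counts, tree3, model, s_max = s_max, root_max = root_max)
  # exhaustive: sum over root and the single internal node state
  tr <- stats::reorder(tree3, "postorder")
  lam <- 0.8
  tp <- function(s, c, t) bd_transition_prob(s, c, t, lam)
  tot <- 0
  for (r in 1:root_max) {
    for (u in 0:s_max) {   # internal node joining B and C
      tot <- tot + (1 / root_max) *
        tp(r, counts[["A"]], 0.4) * tp(r, u, 0.15) *
        tp(u, counts[["B"]], 0.25) * tp(u, counts[["C"]], 0.25)
    }
  }
  expect_equal(got, log(tot), tolerance = 1e-10)

  # two-leaf tree
  tr2 <- read_newick("(X:0.3,Y:0.6);")
  m2 <- bd_model(edge_partition(tr2), c(background = 1.2))
  got2 <- family_loglik(c(X = 1L, Y = 4L), tr2, m2, s_max = 10L, root_max = 4L)
  tot2 <- sum(vapply(1:4, function(r) {
    (1 / 4) * bd_transition_prob(r, 1, 0.3, 1.2) * bd_transition_prob(r, 4, 0.6, 1.2)
  }, numeric(1)))
  expect_equal(got2, log(tot2), tolerance = 1e-10)
})

test_that("identity-rate likelihood and leaf-order invariance hold", {
  model0 <- bd_model(edge_partition(tree3), c(background = 0))
  expect_equal(family_loglik(c(A = 4L, B = 4L, C = 4L), tree3, model0,
                             root_max = 4L),
               log(1 / 4))
  model <- bd_model(edge_partition(tree3), c(background = 0.5))
  l1 <- family_loglik(c(A = 2L, B = 0L, C = 5L), tree3, model)
  l2 <- family_loglik(c(C = 5L, A = 2L, B = 0L), tree3, model)
  expect_equal(l1, l2)
  expect_error(family_loglik(c(A = 0L, B = 0L, C = 0L), tree3, model),
               "all-zero")
})

test_that("single-branch ML lambda matches a grid-search oracle", {
  tr2 <- read_newick("(X:0.5,Y:0.5);")
  mat <- matrix(c(1L, 3L), 1, 2, dimnames = list("f1", c("X", "Y")))
  fit <- fit_lambda(mat, tr2, s_max = 30L, root_max = 3L)
  grid <- exp(seq(log(1e-4), log(20), length.out = 1200))
  ll <- vapply(grid, function(l) {
    m <- bd_model(edge_partition(tr2), c(background = l))
    family_loglik(c(X = 1L, Y = 3L), tr2, m, s_max = 30L, root_max = 3L)
  }, numeric(1))
  expect_equal(unname(fit$model$lambda), grid[which.max(ll)], tolerance = 1e-2)
  expect_gte(fit$model$lambda[[1]], 0)
})

test_that("lambda is recovered within 30 percent from simulated families", {
  tr6 <- read_newick("((A:60,B:60):40,((C:40,D:40):30,(E:50,F:20):50):30);")
  lam_true <- 0.002
  sim <- simulate_family_sizes(tr6, lam_true, 500L, seed = 101)
  keep <- rownames(sim$matrix)[rowSums(sim$matrix) > 0]
  keep <- intersect(keep, parsimony_root_presence(sim$matrix, tr6))
  fit <- fit_lambda(sim$matrix[keep, ], tr6)
  expect_gt(fit$model$lambda[[1]], lam_true * 0.7)
  expect_lt(fit$model$lambda[[1]], lam_true * 1.3)
})

test_that("nested LRT behaves at the boundaries and orders likelihoods", {
  f0 <- structure(list(logL = -100, n_params = 1L), class = "bd_fit")
  f1 <- structure(list(logL = -100, n_params = 2L), class = "bd_fit")
  out <- lrt_nested(f0, f1)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  f2 <- structure(list(logL = -98.08, n_params = 2L), class = "bd_fit")
  out2 <- lrt_nested(f0, f2)
  expect_equal(out2$statistic, 3.84, tolerance = 1e-6)
  expect_equal(out2$p, 0.05, tolerance = 0.002)
  expect_error(lrt_nested(f1, f0), "more parameters")

  # complex model never fits worse than its nested simple model
  tr4 <- read_newick("((A:50,B:50):30,(C:40,D:40):40);")
  sim <- simulate_family_sizes(tr4, 0.003, 80L, seed = 5)
  keep <- intersect(rownames(sim$matrix)[rowSums(sim$matrix) > 0],
                    parsimony_root_presence(sim$matrix, tr4))
  part2 <- edge_partition(tr4, clades = list(ab = c("A", "B")))
  fit1 <- fit_lambda(sim$matrix[keep, ], tr4)
  fit2 <- fit_lambda(sim$matrix[keep, ], tr4, partition = part2)
  expect_gte(fit2$logL, fit1$logL - 1e-4)
})

test_that("ancestral size reconstruction matches exhaustive enumeration", {
  model0 <- bd_model(edge_partition(tree3), c(background = 0))
  rec <- ancestral_sizes(c(A = 4L, B = 4L, C = 4L), tree3, model0)
  expect_true(all(rec$sizes == 4L))
  expect_equal(rec$n_expansions, 0L)
  expect_equal(rec$n_stable, 4L)

  # two-leaf exhaustive: best root state maximises the joint probability
  tr2 <- read_newick("(X:0.3,Y:0.6);")
  m2 <- bd_model(edge_partition(tr2), c(background = 1.0))
  rec2 <- ancestral_sizes(c(X = 1L, Y = 4L), tr2, m2, s_max = 12L, root_max = 4L)
  joint <- vapply(1:4, function(r) {
    bd_transition_prob(r, 1, 0.3, 1) * bd_transition_prob(r, 4, 0.6, 1)
  }, numeric(1))
  expect_equal(rec2$sizes[3], which.max(joint))
  # reconstruction invariant to leaf order
  rec2b <- ancestral_sizes(c(Y = 4L, X = 1L), tr2, m2, s_max = 12L, root_max = 4L)
  expect_equal(rec2$sizes, rec2b$sizes)
})

test_that("binomial expansion test equals the exact closed forms", {
  expect_equal(binomial_expansion_test(3, 3), 1)
  expect_equal(binomial_expansion_test(8, 0), 2 * 0.5^8)
  # exhaustive agreement with direct two-sided enumeration for n <= 12
  for (n in 1:12) {
    for (k in 0:n) {
      probs <- dbinom(0:n, n, 0.5)
      expected <- sum(probs[probs <= dbinom(k, n, 0.5) * (1 + 1e-7)])
      expect_equal(binomial_expansion_test(k, n - k), min(1, expected),
                   tolerance = 1e-9, info = paste(k, n))
    }
  }
})

test_that("expansion counts are normalised by terminal branch length", {
  tr <- read_newick("((A:0.5,B:0.25):0.25,C:0.75);")
  out <- normalize_expansion(c(A = 10, B = 10, C = 9), tr)
  expect_equal(unname(out), c(20, 40, 12))
  tr0 <- read_newick("((A:0,B:0.25):0.25,C:0.75);")
  expect_error(normalize_expansion(c(A = 1), tr0), "zero terminal")
})
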