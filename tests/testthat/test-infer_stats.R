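test_that("lower_triangle uses fixed row-major (row > col) order", {
  M3 <- matrix(1:9, 3, byrow = TRUE)
  expect_equal(lower_triangle(M3), c(M3[2, 1], M3[3, 1], M3[3, 2]))
  M4 <- matrix(1:16, 4, byrow = TRUE)
  expect_equal(lower_triangle(M4),
               c(M4[2, 1], M4[3, 1], M4[3, 2], M4[4, 1], M4[4, 2], M4[4, 3]))
  expect_length(lower_triangle(matrix(0, 2, 2)), 1)
  expect_length(lower_triangle(matrix(0, 38, 38)), 703)
})

test_that("mantel_test recovers perfect and affine-invariant correlation", {
  set.seed(21)
  D <- random_symmetric_matrix(12)
  res <- mantel_test(D, D, n_perm = 99, seed = 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 1 / 100)
  expect_equal(res$n_pairs, 66)

  res2 <- mantel_test(D, 2 * D + 3 - diag(3, 12), n_perm = 49, seed = 1)
  expect_equal(res2$r, 1)

  expect_error(mantel_test(D, matrix(0, 12, 12) + diag(0, 12), n_perm = 9),
               "constant")
})

test_that("mantel_test r is symmetric in its arguments", {
  set.seed(22)
  D1 <- random_symmetric_matrix(10)
  D2 <- random_symmetric_matrix(10)
  expect_equal(mantel_test(D1, D2, n_perm = 9, seed = 3)$r,
               mantel_test(D2, D1, n_perm = 9, seed = 3)$r)
})

test_that("mantel_test statistic matches vegan::mantel", {
  set.seed(23)
  D1 <- random_symmetric_matrix(15)
  D2 <- random_symmetric_matrix(15)
  ref <- vegan::mantel(as.dist(D1), as.dist(D2), permutations = 99)
  expect_equal(mantel_test(D1, D2, n_perm = 9, seed = 1)$r,
               unname(ref$statistic), tolerance = 1e-12)
})

test_that("mantel_test is reproducible under a seed", {
  set.seed(24)
  D1 <- random_symmetric_matrix(10)
  D2 <- random_symmetric_matrix(10)
  a <- mantel_test(D1, D2, n_perm = 199, seed = 42)
  b <- mantel_test(D1, D2, n_perm = 199, seed = 42)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 200)
})

test_that("blomberg_k matches phytools::phylosig on the K statistic", {
  set.seed(30)
  tr <- ape::rphylo(40, 1, 0)
  x <- ape::rTraitCont(tr, model = "BM", sigma = 1)
  ours <- blomberg_k(tr, x, n_perm = 0)
  ref <- phytools::phylosig(tr, x, method = "K")
  expect_equal(ours$k, unname(as.numeric(ref)), tolerance = 1e-8)
  # star tree: V diagonal, K still finite
  star <- read_newick("(A:1,B:1,C:1,D:1,E:1);")
  xs <- stats::setNames(rnorm(5), star$tip.label)
  expect_true(is.finite(blomberg_k(star, xs, n_perm = 0)$k))
})

test_that("blomberg_k validates input and is seed-reproducible", {
  tr <- ape::rphylo(10, 1, 0)
  x <- stats::setNames(rep(1, 10), tr$tip.label)
  expect_error(blomberg_k(tr, x), "zero-variance")
  y <- stats::setNames(rnorm(10), tr$tip.label)
  expect_error(blomberg_k(tr, y[1:5]), "cover every tip")
  a <- blomberg_k(tr, y, n_perm = 99, seed = 7)
  b <- blomberg_k(tr, y, n_perm = 99, seed = 7)
  expect_identical(a$p, b$p)
  expect_gte(a$p, 1 / 100)
})

test_that("plotwise_mean_beta averages the pairs containing each plot", {
  comm <- toy_community(
    list(p1 = c("A", "B"), p2 = c("B", "C"), p3 = c("A", "C")),
    category = rep("interior", 3)
  )
  fb <- beta_matrix(comm, "taxonomic")
  pm <- plotwise_mean_beta(fb, "beta_total")
  expect_equal(pm$value, rep(2 / 3, 3))

  # identical plots: all-zero means
  same <- toy_community(list(p1 = "A", p2 = "A", p3 = "A"))
  expect_equal(plotwise_mean_beta(beta_matrix(same, "taxonomic"))$value,
               rep(0, 3))
})

test_that("plotwise means match direct averaging and conserve the grand mean", {
  set.seed(40)
  occ <- matrix(rbinom(6 * 12, 1, 0.5), 6, 12,
                dimnames = list(paste0("p", 1:6), paste0("sp", 1:12)))
  occ[rowSums(occ) == 0, 1] <- 1L
  comm <- toy_community(apply(occ, 1, function(r) paste0("sp", which(r == 1)),
                              simplify = FALSE))
  fb <- beta_matrix(comm, "taxonomic")
  pm <- plotwise_mean_beta(fb, "beta_total")
  M <- fb$matrices$beta_total
  for (p in rownames(M)) {
    expect_equal(pm$value[pm$plot_id == p], mean(M[p, setdiff(rownames(M), p)]))
  }
  # mean of per-plot means equals the pair mean (each pair counted twice)
  expect_equal(mean(pm$value), mean(lower_triangle(M)))
})

test_that("percent_change reports decreases relative to the interior mean", {
  cmp <- percent_change(rep(0.5, 6), rep(0.45, 6), n_perm = 99, seed = 1)
  g <- glance(cmp)
  expect_equal(g$percent_change, 10)
  expect_equal(g$interior_mean, 0.5)
  eq <- percent_change(rep(0.4, 6), rep(0.4, 6), n_perm = 99, seed = 1)
  expect_equal(glance(eq)$percent_change, 0)
  expect_equal(glance(eq)$p.value, 1)
  expect_error(percent_change(rep(0, 5), rep(0.1, 5)), "interior mean is 0")
  expect_error(percent_change(1:5, 1:4), "equal length")
})

test_that("paired_signflip_test resolves extreme and null cases", {
  expect_lte(paired_signflip_test(rep(0.1, 10), n_perm = 9999, seed = 1), 0.01)
  alt <- rep(c(0.1, -0.1), 5)
  expect_gte(paired_signflip_test(alt, n_perm = 999, seed = 1), 0.5)
  expect_equal(paired_signflip_test(rep(0, 8), n_perm = 99), 1)
  expect_error(paired_signflip_test(c(1, 2), n_perm = 9), "at least 5")
  set.seed(6)
  d <- rnorm(10)
  a <- paired_signflip_test(d, n_perm = 199, seed = 5)
  b <- paired_signflip_test(d, n_perm = 199, seed = 5)
  expect_identical(a, b)
  expect_gte(a, 1 / 200)
})
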