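make_mixed_traits <- function(n_species, n_quant = 3, n_cat = 2,
                              missing_rate = 0.15) {
  df <- data.frame(species_id = paste0("s", seq_len(n_species)))
  types <- character(0)
  for (i in seq_len(n_quant)) {
    nm <- paste0("q", i)
    df[[nm]] <- rnorm(n_species, sd = i)
    types[nm] <- "quantitative"
  }
  for (i in seq_len(n_cat)) {
    nm <- paste0("k", i)
    df[[nm]] <- sample(letters[1:3], n_species, replace = TRUE)
    types[nm] <- "categorical"
  }
  for (nm in names(types)) {
    miss <- runif(n_species) < missing_rate
    df[[nm]][miss] <- NA
  }
  # guarantee every pair keeps at least one usable trait
  df$q1[is.na(df$q1)] <- 0
  trait_table(df, types)
}

test_that("gower_distance matches hand-computed mixed-trait cases", {
  tt <- trait_table(
    data.frame(species_id = paste0("s", 1:4), size = c(0, 2, 7, 10)),
    c(size = "quantitative")
  )
  D <- gower_distance(tt)
  expect_equal(D["s2", "s3"], 0.5)  # |2-7| / range 10

  tt2 <- trait_table(
    data.frame(species_id = paste0("s", 1:4), size = c(0, 2, 7, 10),
               colr = c("x", "x", "y", "y")),
    c(size = "quantitative", colr = "categorical")
  )
  expect_equal(gower_distance(tt2)["s2", "s3"], (0.5 + 1) / 2)

  same <- trait_table(
    data.frame(species_id = c("a", "b"), q = c(3, 3), k = c("z", "z")),
    c(q = "quantitative", k = "categorical")
  )
  expect_warning(D0 <- gower_distance(same), "constant")
  expect_equal(D0["a", "b"], 0)
})

test_that("gower_distance skips missing traits and renormalizes", {
  tt <- trait_table(
    data.frame(species_id = c("A", "B"), t1 = c(0, 10), t2 = c(NA, "x")),
    c(t1 = "quantitative", t2 = "categorical")
  )
  expect_equal(gower_distance(tt)["A", "B"], 1)  # only t1 usable

  none <- trait_table(
    data.frame(species_id = c("A", "B", "C"), t1 = c(1, NA, 2),
               t2 = c(NA, "x", "y")),
    c(t1 = "quantitative", t2 = "categorical")
  )
  expect_error(gower_distance(none), "'A' vs 'B'")
})

test_that("gower_distance equals the per-pair loop oracle on random tables", {
  set.seed(101)
  for (rep in 1:5) {
    tt <- make_mixed_traits(20)
    D <- gower_distance(tt)
    expect_equal(D, oracle_gower(tt$data, tt$types), tolerance = 1e-12)
    expect_true(all(D >= 0 & D <= 1))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
  }
})

test_that("gower_distance agrees with cluster::daisy on complete data", {
  set.seed(11)
  tt <- make_mixed_traits(15, missing_rate = 0)
  df <- as.data.frame(tt$data[-1])
  for (nm in names(tt$types)[tt$types == "categorical"]) {
    df[[nm]] <- factor(df[[nm]])
  }
  rownames(df) <- tt$data$species_id
  ref <- as.matrix(cluster::daisy(df, metric = "gower"))
  expect_equal(unname(gower_distance(tt)), unname(ref), tolerance = 1e-10)
})

test_that("prune_correlated drops correlated columns greedily and is idempotent", {
  set.seed(3)
  x <- rnorm(100)
  df <- tibble::tibble(C1 = x, C2 = x, C3 = rnorm(100))
  expect_equal(prune_correlated(df, 0.5), c("C1", "C3"))
  # idempotence
  expect_equal(prune_correlated(df[c("C1", "C3")], 0.5), c("C1", "C3"))
  # pearson route
  expect_equal(prune_correlated(df, 0.5, method = "pearson"), c("C1", "C3"))
  expect_error(prune_correlated(tibble::tibble(a = 1:5, b = letters[1:5])),
               "non-quantitative")
})

test_that("independent columns survive pruning in nearly all replicates", {
  kept_both <- vapply(1:100, function(s) {
    set.seed(s)
    df <- tibble::tibble(a = rnorm(200), b = rnorm(200))
    length(prune_correlated(df, 0.5)) == 2
  }, logical(1))
  expect_gte(mean(kept_both), 0.95)
})

test_that("upgma reproduces the textbook three-taxon dendrogram", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- upgma(D)
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 4)
  # A-B join height 1, root height 2 (= half the merge distances)
  depths <- ape::node.depth.edgelength(tr)
  expect_equal(max(depths[1:3]), 2)
  expect_true(ape::is.ultrametric(tr, tol = 1e-9))
})

test_that("upgma on an equidistant matrix puts all tips at d/2", {
  D <- matrix(3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(D) <- 0
  tr <- upgma(D)
  depths <- ape::node.depth.edgelength(tr)[1:4]
  expect_equal(unname(depths), rep(1.5, 4))
})

test_that("upgma cophenetics equal an O(n^3) naive reimplementation", {
  set.seed(2024)
  for (rep in 1:5) {
    D <- random_symmetric_matrix(12)
    tr <- upgma(D)
    coph <- ape::cophenetic.phylo(tr)[rownames(D), rownames(D)]
    expect_equal(coph, oracle_upgma_cophenetic(D), tolerance = 1e-9)
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
    # cophenetic range is bracketed by the input distances
    off <- D[lower.tri(D)]
    expect_gte(min(coph[lower.tri(coph)]), min(off) - 1e-12)
    expect_lte(max(coph[lower.tri(coph)]), max(off) + 1e-12)
  }
})

test_that("upgma rejects NaN matrices", {
  D <- random_symmetric_matrix(4)
  D[1, 2] <- D[2, 1] <- NaN
  expect_error(upgma(D), "NA|NaN")
})
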