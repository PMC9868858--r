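test_that("species_abc counts shared and unique species", {
  expect_equal(species_abc(c("A", "B"), c("B", "C")),
               tibble::tibble(a = 1, b = 1, c = 1))
  expect_equal(species_abc(letters[1:5], letters[1:5]),
               tibble::tibble(a = 5, b = 0, c = 0))
  expect_equal(species_abc(c("x", "y"), c("p", "q", "r")),
               tibble::tibble(a = 0, b = 2, c = 3))
  expect_error(species_abc(character(0), "A"), "nonempty")
})

test_that("jaccard_partition applies the printed formulas", {
  expect_equal(jaccard_partition(1, 1, 1),
               tibble::tibble(beta_total = 2 / 3, beta_repl = 2 / 3,
                              beta_rich = 0))
  expect_equal(jaccard_partition(0, 3, 0),
               tibble::tibble(beta_total = 1, beta_repl = 0, beta_rich = 1))
  expect_equal(jaccard_partition(5, 0, 0),
               tibble::tibble(beta_total = 0, beta_repl = 0, beta_rich = 0))
  expect_equal(jaccard_partition(2, 3, 1),
               tibble::tibble(beta_total = 4 / 6, beta_repl = 2 / 6,
                              beta_rich = 2 / 6))
  expect_error(jaccard_partition(0, 0, 0), "positive")
  expect_error(jaccard_partition(-1, 1, 1), "nonnegative")
})

test_that("replacement and richness difference always sum to total", {
  set.seed(99)
  abc <- tibble::tibble(a = runif(1000, 0, 50), b = runif(1000, 0, 50),
                        c = runif(1000, 0, 50))
  bt <- jaccard_partition(abc)
  expect_true(all(abs(bt$beta_repl + bt$beta_rich - bt$beta_total) < 1e-12))
  expect_true(all(bt$beta_total >= 0 & bt$beta_total <= 1))
  # symmetry under swapping the two communities
  swapped <- jaccard_partition(abc$a, abc$c, abc$b)
  expect_equal(bt$beta_total, swapped$beta_total)
  expect_equal(bt$beta_repl, swapped$beta_repl)
  expect_equal(bt$beta_rich, swapped$beta_rich)
})

test_that("branch_abc resolves hand-enumerable trees", {
  star <- read_newick("(A:1,B:1,C:1);")
  expect_equal(branch_abc(c("A", "B"), c("B", "C"), star),
               tibble::tibble(a = 1, b = 1, c = 1))

  cat3 <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(branch_abc(c("A", "B"), "C", cat3),
               tibble::tibble(a = 0, b = 3, c = 2))
  # identical communities: everything shared
  res <- branch_abc(c("A", "B"), c("A", "B"), cat3)
  expect_equal(res, tibble::tibble(a = 3, b = 0, c = 0))
  expect_error(branch_abc("A", "Z", cat3), "missing from tree: Z")
})

test_that("branch_abc equals the explicit edge-set oracle on random trees", {
  set.seed(31)
  for (rep in 1:30) {
    tr <- ape::rtree(30)
    bi <- branch_incidence(tr)
    c1 <- random_community_set(tr$tip.label)
    c2 <- random_community_set(tr$tip.label)
    got <- branch_abc(c1, c2, tr, incidence = bi)
    want <- oracle_branch_abc(c1, c2, tr)
    expect_equal(unlist(got), want, tolerance = 1e-12)
  }
})

test_that("branch sets can be rescoped to the pair MRCA clade", {
  cat3 <- read_newick("((A:1,B:1):1,C:2);")
  # A vs B: the cherry's stem is outside the MRCA scope
  expect_equal(branch_abc("A", "B", cat3, mrca_rescope = TRUE),
               tibble::tibble(a = 0, b = 1, c = 1))
  # global-root default keeps the shared stem
  expect_equal(branch_abc("A", "B", cat3),
               tibble::tibble(a = 1, b = 1, c = 1))
})

test_that("mpd_between matches closed forms and the double-loop oracle", {
  star <- read_newick("(A:1,B:1,C:1);")
  expect_equal(mpd_between("A", "B", star), 2)
  expect_equal(mpd_between(c("A", "B"), c("A", "B"), star), 1) # (0+2+2+0)/4
  # exclude-shared variant averages distinct pairs only
  expect_equal(mpd_between(c("A", "B"), c("A", "B"), star,
                           exclude_shared = TRUE), 2)
  # closed form: community vs itself on a unit star = 2L(S-1)/S
  starL <- read_newick("(A:3,B:3,C:3,D:3);")
  S <- 4
  expect_equal(mpd_between(LETTERS[1:4], LETTERS[1:4], starL),
               2 * 3 * (S - 1) / S)
  set.seed(77)
  for (rep in 1:20) {
    tr <- ape::rtree(15)
    c1 <- random_community_set(tr$tip.label)
    c2 <- random_community_set(tr$tip.label)
    expect_equal(mpd_between(c1, c2, tr), oracle_mpd_between(c1, c2, tr),
                 tolerance = 1e-10)
  }
})

test_that("mpd_between agrees with picante::comdist", {
  set.seed(5)
  tr <- ape::rtree(12)
  c1 <- sample(tr$tip.label, 5)
  c2 <- sample(tr$tip.label, 6)
  occ <- rbind(p1 = as.integer(tr$tip.label %in% c1),
               p2 = as.integer(tr$tip.label %in% c2))
  colnames(occ) <- tr$tip.label
  ref <- as.matrix(picante::comdist(occ, ape::cophenetic.phylo(tr),
                                    abundance.weighted = FALSE))["p1", "p2"]
  expect_equal(mpd_between(c1, c2, tr), ref, tolerance = 1e-10)
})

test_that("beta_matrix is zero for identical plots and masks cross-category pairs", {
  comm <- toy_community(
    list(p1 = c("a", "b"), p2 = c("a", "b"), p3 = c("a", "b"),
         q1 = c("a", "c")),
    category = c("interior", "interior", "interior", "roadside")
  )
  fb <- beta_matrix(comm, "taxonomic")
  M <- fb$matrices$beta_total
  expect_equal(M["p1", "p2"], 0)
  expect_equal(M["p1", "p3"], 0)
  expect_true(is.na(M["p1", "q1"]))
  expect_equal(M["p1", "p1"], 0)
})

test_that("unit-branch star tree reduces branch beta to species beta", {
  set.seed(55)
  for (rep in 1:5) {
    species <- paste0("sp", 1:25)
    occ <- matrix(rbinom(10 * 25, 1, 0.4), 10, 25,
                  dimnames = list(paste0("p", 1:10), species))
    occ[rowSums(occ) == 0, 1] <- 1L
    meta <- tibble::tibble(plot_id = rownames(occ),
                           site_id = paste0("s", 1:10), road_id = "r",
                           category = rep(c("interior", "roadside"), each = 5))
    comm <- community_matrix(occ, meta)
    star <- read_newick(paste0("(", paste0(species, ":1", collapse = ","), ");"))
    tax <- beta_matrix(comm, "taxonomic")
    phy <- beta_matrix(comm, "phylogenetic", tree = star)
    for (co in c("beta_total", "beta_repl", "beta_rich")) {
      d <- abs(tax$matrices[[co]] - phy$matrices[[co]])
      expect_lt(max(d, na.rm = TRUE), 1e-12)
    }
  }
})

test_that("bwpbd matrix entries equal mpd_between per pair", {
  set.seed(8)
  tr <- ape::rtree(10)
  occ <- matrix(rbinom(4 * 10, 1, 0.5), 4, 10,
                dimnames = list(paste0("p", 1:4), tr$tip.label))
  occ[rowSums(occ) == 0, 1] <- 1L
  comm <- toy_community(apply(occ, 1, function(r) tr$tip.label[r == 1],
                              simplify = FALSE))
  fb <- beta_matrix(comm, "phylogenetic", tree = tr)
  sp <- function(p) colnames(comm$occupancy)[comm$occupancy[p, ] == 1]
  for (pair in list(c("p1", "p2"), c("p1", "p4"), c("p2", "p3"))) {
    expect_equal(fb$matrices$bwpbd[pair[1], pair[2]],
                 mpd_between(sp(pair[1]), sp(pair[2]), tr), tolerance = 1e-10)
  }
})

test_that("pool and shared-species monotonicity hold", {
  c1 <- c("a", "b", "c")
  c2 <- c("b", "d")
  base <- jaccard_partition(species_abc(c1, c2))
  # adding a species absent from both changes nothing (pool irrelevant)
  expect_equal(jaccard_partition(species_abc(c1, c2)), base)
  # adding a shared species weakly decreases beta_total
  richer <- jaccard_partition(species_abc(c(c1, "z"), c(c2, "z")))
  expect_lte(richer$beta_total, base$beta_total)
})

test_that("euclidean_distance_matrix is |x_p - x_q| with category masking", {
  soil <- tibble::tibble(plot_id = c("p1", "p2", "p3"),
                         pH = c(6.36, 7.01, 6.36))
  D <- euclidean_distance_matrix(soil, "pH")
  expect_equal(D["p1", "p2"], 0.65)
  expect_equal(D["p1", "p3"], 0)
  expect_error(euclidean_distance_matrix(soil, "EC"), "unknown soil variable")

  meta <- tibble::tibble(plot_id = c("p1", "p2", "p3"),
                         category = c("interior", "roadside", "interior"))
  Dm <- euclidean_distance_matrix(soil, "pH", meta)
  expect_true(is.na(Dm["p1", "p2"]))
  expect_equal(Dm["p1", "p3"], 0)

  set.seed(12)
  x <- runif(8)
  soil2 <- tibble::tibble(plot_id = paste0("p", 1:8), v = x)
  D2 <- euclidean_distance_matrix(soil2, "v")
  for (i in 1:8) for (j in 1:8) {
    expect_equal(D2[i, j], abs(x[i] - x[j]))
  }
})
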