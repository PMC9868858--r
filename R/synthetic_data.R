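#' Configuration for the paired-design community simulator
#'
#' Bundles every knob of the synthetic study: a Yule species pool, Brownian
#' traits (with optional signal-free shuffled traits), paired
#' roadside/interior plots assembled by Gaussian environmental filtering, and
#' road-shifted soil variables. The defaults emulate the reference survey
#' design: 38 paired sites (76 plots) along three roads, a 300-species pool,
#' 12 traits (9 quantitative + 3 categorical), and roadside conditions that
#' are both shifted (mean) and narrowed (smaller spread) relative to interior
#' ones - the environmental-filtering mechanism that produces biotic
#' homogenization. Soil defaults shift roadside pH up (6.36 -> 7.01), bulk
#' density up and total nitrogen down.
#'
#' The environment and niche optima share one scale: a species' optimum is
#' its first Brownian trait value (tip standard deviation about 2.4 under
#' the default tree), plots draw an environment value, and species occupy a
#' plot with probability `p_max * exp(-(e - mu)^2 / (2 w^2))`. Narrower
#' roadside environments (`env_roadside_sd < env_interior_sd`) make roadside
#' plots more alike, lowering their beta diversity.
#'
#' @param n_species Species-pool size (>= 4). Default 300.
#' @param birth_rate Yule birth rate. Default 1.
#' @param n_sites Number of paired sites (>= 2). Default 38.
#' @param n_quantitative,n_categorical Numbers of quantitative and
#'   categorical traits. Defaults 9 and 3 (12 total).
#' @param n_levels Levels per categorical trait. Default 4.
#' @param sigma2 Brownian rate for all traits. Default 1.
#' @param shuffled_traits Names of traits simulated without phylogenetic
#'   signal (tip-shuffled after simulation). Default `"trait09"`.
#' @param missing_rate Fraction of trait cells blanked at random (never the
#'   niche trait). Default 0.02.
#' @param niche_trait Which trait supplies niche optima. Default `"trait01"`.
#' @param niche_width Gaussian niche width `w` (> 0). Default 1.5.
#' @param env_interior_mean,env_interior_sd Interior plot environment
#'   distribution. Defaults 0 and 1.
#' @param env_roadside_mean,env_roadside_sd Roadside plot environment
#'   distribution; filtering requires `env_roadside_sd <= env_interior_sd`.
#'   Defaults 0.5 and 0.4.
#' @param p_max Occupancy probability ceiling in (0, 1]. Default 0.7.
#' @param filtering When `FALSE`, roadside environment parameters are reset
#'   to the interior ones and soil category means are equalized - the null
#'   (no road effect) configuration. Default `TRUE`.
#' @param soil Tibble with columns `variable`, `interior_mean`,
#'   `roadside_mean`, `sd`; `NULL` uses the built-in defaults.
#' @param seed Master seed; component substreams (tree, traits, communities,
#'   soil) derive from it by fixed offsets.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_species = 300, birth_rate = 1, n_sites = 38,
                       n_quantitative = 9, n_categorical = 3, n_levels = 4,
                       sigma2 = 1, shuffled_traits = "trait09",
                       missing_rate = 0.02, niche_trait = "trait01",
                       niche_width = 1.5,
                       env_interior_mean = 0, env_interior_sd = 1,
                       env_roadside_mean = 0.5, env_roadside_sd = 0.4,
                       p_max = 0.7, filtering = TRUE, soil = NULL,
                       seed = 1) {
  if (n_species < 4) abort("n_species must be >= 4")
  if (n_sites < 2) abort("n_sites must be >= 2")
  if (niche_width <= 0) abort("niche_width must be > 0")
  if (p_max <= 0 || p_max > 1) abort("p_max must be in (0, 1]")
  if (env_interior_sd < 0 || env_roadside_sd < 0) abort("environment SDs must be >= 0")
  if (!filtering) {
    env_roadside_mean <- env_interior_mean
    env_roadside_sd <- env_interior_sd
  }
  if (is.null(soil)) soil <- default_soil_spec(filtering)
  soil <- as_tibble(soil)
  stopifnot(all(c("variable", "interior_mean", "roadside_mean", "sd") %in% names(soil)))
  if (any(soil$sd < 0)) abort("soil SDs must be >= 0")
  structure(
    list(
      n_species = n_species, birth_rate = birth_rate, n_sites = n_sites,
      n_quantitative = n_quantitative, n_categorical = n_categorical,
      n_levels = n_levels, sigma2 = sigma2, shuffled_traits = shuffled_traits,
      missing_rate = missing_rate, niche_trait = niche_trait,
      niche_width = niche_width,
      env_interior_mean = env_interior_mean, env_interior_sd = env_interior_sd,
      env_roadside_mean = env_roadside_mean, env_roadside_sd = env_roadside_sd,
      p_max = p_max, filtering = filtering, soil = soil, seed = seed
    ),
    class = "sim_config"
  )
}

default_soil_spec <- function(filtering = TRUE) {
  s <- tibble(
    variable      = c("pH", "EC", "SOM", "TN", "TP", "AP", "NH4N", "NO3N", "CEC", "BK"),
    interior_mean = c(6.36, 150,  80,    3.0,  0.60, 12,   8,      6,      18,    0.90),
    roadside_mean = c(7.01, 180,  95,    2.2,  0.60, 14,   8,      9,      18,    1.15),
    sd            = c(0.25, 30,   15,    0.5,  0.12, 3,    2,      2,      3,     0.12)
  )
  if (!filtering) s$roadside_mean <- s$interior_mean
  s
}

# fixed offsets giving each component its own reproducible substream
substream_seed <- function(seed, component) {
  offs <- c(tree = 11L, traits = 23L, communities = 37L, soil = 53L)
  as.integer(seed) + offs[[component]]
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Constant-rate pure-birth tree with exponentially distributed waiting
#' times, conditioned on `n` extant tips, labelled `sp1...spn`. Stands in
#' for a pruned regional mega-tree as the species pool's phylogeny.
#'
#' @param n Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0). Default 1.
#' @param seed Optional integer seed.
#' @return An ultrametric `phylo` tree with positive branch lengths.
#' @export
simulate_yule_tree <- function(n, birth_rate = 1, seed = NULL) {
  if (n < 2) abort("n must be >= 2")
  if (birth_rate <= 0) abort("birth_rate must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n, birth = birth_rate, death = 0)
  tree$tip.label <- paste0("sp", seq_len(n))
  tree
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Root value 0; along each branch the value steps by
#' `Normal(0, sigma2 * branch_length)`. Tip values carry phylogenetic signal
#' with Blomberg's K of 1 in expectation.
#'
#' @param tree `phylo` tree.
#' @param sigma2 Brownian rate (variance per unit branch length). Default 1.
#' @param seed Optional integer seed.
#' @return Named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(tree, sigma2 = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (sigma2 < 0) abort("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (sigma2 == 0) {
    return(setNames(rep(0, length(tree$tip.label)), tree$tip.label))
  }
  ape::rTraitCont(tree, model = "BM", sigma = sqrt(sigma2), root.value = 0)
}

#' Discretize a continuous trait into ordered quantile bins
#'
#' Used to derive categorical traits from Brownian ones so categorical
#' columns still carry (attenuated) phylogenetic signal.
#'
#' @param values Named numeric vector.
#' @param k Number of bins (>= 2).
#' @return Named character vector with levels `lvl1 < ... < lvlk`.
#' @export
discretize_trait <- function(values, k) {
  if (k < 2) abort("k must be >= 2")
  if (length(unique(values)) < k) {
    abort(paste0("fewer than ", k, " distinct values: cannot form ", k, " bins"))
  }
  brk <- quantile(values, probs = seq(0, 1, length.out = k + 1), names = FALSE)
  if (anyDuplicated(brk)) abort("tied quantile breaks: reduce k")
  out <- cut(values, breaks = brk, include.lowest = TRUE,
             labels = paste0("lvl", seq_len(k)))
  setNames(as.character(out), names(values))
}

#' Simulate the full mixed trait table for a species pool
#'
#' Quantitative traits are independent Brownian simulations; categorical
#' traits are quantile-discretized Brownian simulations; traits listed in
#' `shuffled_traits` have their tip values randomly permuted, destroying
#' their phylogenetic signal while keeping the marginal distribution. A
#' small fraction of cells (never the niche trait) is blanked to exercise
#' missing-data handling.
#'
#' @param tree `phylo` species pool.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (defaults to the config's traits
#'   substream).
#' @return A [trait_table()].
#' @export
simulate_traits <- function(tree, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% substream_seed(config$seed, "traits")
  set.seed(seed)
  n_q <- config$n_quantitative
  n_c <- config$n_categorical
  nm <- sprintf("trait%02d", seq_len(n_q + n_c))
  cols <- list()
  types <- character(0)
  for (i in seq_len(n_q)) {
    cols[[nm[i]]] <- simulate_bm_trait(tree, config$sigma2)
    types[nm[i]] <- "quantitative"
  }
  for (i in seq_len(n_c)) {
    j <- n_q + i
    cols[[nm[j]]] <- discretize_trait(simulate_bm_trait(tree, config$sigma2),
                                      config$n_levels)
    types[nm[j]] <- "categorical"
  }
  for (tr in intersect(config$shuffled_traits, nm)) {
    cols[[tr]] <- setNames(sample(cols[[tr]]), names(cols[[tr]]))
  }
  df <- tibble(species_id = tree$tip.label)
  for (tr in nm) df[[tr]] <- unname(cols[[tr]][tree$tip.label])
  if (config$missing_rate > 0) {
    for (tr in setdiff(nm, config$niche_trait)) {
      miss <- runif(nrow(df)) < config$missing_rate
      df[[tr]][miss] <- NA
    }
  }
  trait_table(df, types)
}

#' Assemble paired roadside/interior communities by environmental filtering
#'
#' Each site draws one interior environment value and one roadside one from
#' the category's Normal distribution; species `s` then occupies the plot
#' independently with probability `p_max * exp(-(e - mu_s)^2 / (2 w^2))`,
#' where `mu_s` is the species' niche-trait value. An empty plot is redrawn
#' (environment and occupancy) up to 100 times before erroring. With
#' `env_roadside_sd < env_interior_sd` roadside plots sample a narrower
#' slice of environmental space - the filtering that homogenizes them.
#'
#' @param tree `phylo` species pool (tip labels = species ids).
#' @param traits A [trait_table()] containing the niche trait with no
#'   missing values.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (defaults to the communities
#'   substream).
#' @return A paired [community_matrix()] with plots `site01_interior`,
#'   `site01_roadside`, ...
#' @export
simulate_communities <- function(tree, traits, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(traits, "trait_table"))
  seed <- seed %||% substream_seed(config$seed, "communities")
  set.seed(seed)
  mu <- setNames(traits$data[[config$niche_trait]], traits$data$species_id)
  if (anyNA(mu)) abort("niche trait must have no missing values")
  species <- tree$tip.label
  mu <- mu[species]
  n_sites <- config$n_sites
  sites <- sprintf("site%02d", seq_len(n_sites))
  roads <- if (n_sites == 38) {
    rep(c("G318", "G350", "G351"), c(5, 16, 17))
  } else {
    paste0("road", rep_len(1:3, n_sites))
  }
  w2 <- 2 * config$niche_width^2
  draw_plot <- function(e_mean, e_sd) {
    for (attempt in seq_len(100)) {
      e <- rnorm(1, e_mean, e_sd)
      occ <- runif(length(species)) < config$p_max * exp(-(e - mu)^2 / w2)
      if (any(occ)) return(as.integer(occ))
    }
    abort("could not draw a nonempty plot in 100 attempts (filtering too strict)")
  }
  rows <- list()
  meta <- list()
  for (s in seq_len(n_sites)) {
    for (cat in c("interior", "roadside")) {
      if (cat == "interior") {
        occ <- draw_plot(config$env_interior_mean, config$env_interior_sd)
      } else {
        occ <- draw_plot(config$env_roadside_mean, config$env_roadside_sd)
      }
      pid <- paste0(sites[s], "_", cat)
      rows[[pid]] <- occ
      meta[[pid]] <- tibble(plot_id = pid, site_id = sites[s],
                            road_id = roads[s], category = cat)
    }
  }
  occupancy <- do.call(rbind, rows)
  colnames(occupancy) <- species
  community_matrix(occupancy, dplyr::bind_rows(meta))
}

#' Simulate road-shifted soil variables
#'
#' Per plot, each soil variable draws `Normal(mean_category, sd)` from the
#' config's soil spec. Defaults place roadside pH at 7.01 vs interior 6.36,
#' roadside bulk density higher and roadside total nitrogen lower.
#'
#' @param meta Plot metadata tibble (`plot_id`, `category`), e.g.
#'   `comm$meta`.
#' @param config A [sim_config()].
#' @param seed Optional integer seed (defaults to the soil substream).
#' @return A soil tibble (`plot_id` + one numeric column per variable).
#' @export
simulate_soil <- function(meta, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% substream_seed(config$seed, "soil")
  set.seed(seed)
  out <- tibble(plot_id = meta$plot_id)
  is_road <- meta$category == "roadside"
  for (i in seq_len(nrow(config$soil))) {
    spec <- config$soil[i, ]
    m <- ifelse(is_road, spec$roadside_mean, spec$interior_mean)
    out[[spec$variable]] <- rnorm(nrow(meta), m, spec$sd)
  }
  out
}

#' Simulate a complete synthetic study
#'
#' Runs the four generators off independent substreams of the master seed:
#' Yule tree, Brownian trait table, filtered paired communities, and
#' road-shifted soils.
#'
#' @param config A [sim_config()].
#' @return Object of class `road_sim`: list with `tree`, `traits`, `comm`,
#'   `soil`, `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                             seed = substream_seed(config$seed, "tree"))
  traits <- simulate_traits(tree, config)
  comm <- simulate_communities(tree, traits, config)
  soil <- simulate_soil(comm$meta, config)
  structure(list(tree = tree, traits = traits, comm = comm, soil = soil,
                 config = config),
            class = "road_sim")
}

#' @export
print.road_sim <- function(x, ...) {
  cat("<road_sim> ", length(x$tree$tip.label), " species, ",
      nrow(x$comm$occupancy), " plots (", x$config$n_sites, " paired sites), ",
      length(x$traits$types), " traits, seed ", x$config$seed, "\n", sep = "")
  invisible(x)
}

#' Write a simulated study to the on-disk input formats
#'
#' Emits exactly what the readers consume: `tree.nwk` (Newick),
#' `community.csv`, `traits.csv` + `traits_types.csv`, `soil.csv`.
#'
#' @param sim A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of paths, invisibly.
#' @export
write_sim_inputs <- function(sim, dir) {
  stopifnot(inherits(sim, "road_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    tree = file.path(dir, "tree.nwk"),
    community = file.path(dir, "community.csv"),
    traits = file.path(dir, "traits.csv"),
    soil = file.path(dir, "soil.csv")
  )
  write_newick(sim$tree, paths[["tree"]])
  write_community_matrix(sim$comm, paths[["community"]])
  write_trait_table(sim$traits, paths[["traits"]])
  write_soil_table(sim$soil, paths[["soil"]])
  invisible(paths)
}
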