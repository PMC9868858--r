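#' Analysis configuration for [run_study()]
#'
#' @param prune_threshold Correlation magnitude above which quantitative
#'   trait / soil columns are dropped before the functional space and the
#'   soil exports. Default 0.5.
#' @param cor_method Correlation used for pruning (`"spearman"` default).
#' @param n_perm_mantel Mantel permutations. Default 999.
#' @param n_perm_signflip Sign-flip permutations for the paired category
#'   comparison. Default 9999.
#' @param n_perm_signal Tip shuffles for Blomberg's K. Default 999.
#' @param exclude_shared_mpd Exclude same-species pairs from the
#'   between-community MPD (default `FALSE`: shared species enter as
#'   zero-distance pairs).
#' @param mantel_pooled Correlate pair vectors pooled across the two
#'   categories instead of per category (default `FALSE`).
#' @param mrca_rescope Rescope branch sets to each pair's MRCA clade
#'   (default `FALSE`: branch sets run from the global root).
#' @param seed Master seed for every permutation stream.
#' @return An object of class `run_config`.
#' @export
run_config <- function(prune_threshold = 0.5,
                       cor_method = c("spearman", "pearson"),
                       n_perm_mantel = 999, n_perm_signflip = 9999,
                       n_perm_signal = 999, exclude_shared_mpd = FALSE,
                       mantel_pooled = FALSE, mrca_rescope = FALSE,
                       seed = 1) {
  cor_method <- match.arg(cor_method)
  if (prune_threshold <= 0 || prune_threshold > 1) {
    abort("prune_threshold must be in (0, 1]")
  }
  if (any(c(n_perm_mantel, n_perm_signflip, n_perm_signal) < 1)) {
    abort("permutation counts must be >= 1")
  }
  structure(
    list(prune_threshold = prune_threshold, cor_method = cor_method,
         n_perm_mantel = n_perm_mantel, n_perm_signflip = n_perm_signflip,
         n_perm_signal = n_perm_signal,
         exclude_shared_mpd = exclude_shared_mpd,
         mantel_pooled = mantel_pooled, mrca_rescope = mrca_rescope,
         seed = seed),
    class = "run_config"
  )
}

facet_suffix <- c(taxonomic = "tax", functional = "func", phylogenetic = "phy")

#' Run the full three-facet beta-diversity study
#'
#' End-to-end pipeline: (1) obtain inputs (a [simulate_study()] result, a
#' [sim_config()] to simulate from, or named file paths); (2) prune
#' correlated quantitative traits, build the Gower functional space and its
#' UPGMA dendrogram; (3) compute taxonomic, functional and phylogenetic
#' Jaccard beta partitions plus basal-weighted PBD for every within-category
#' plot pair; (4) per-plot mean beta, roadside-vs-interior percent change
#' and paired sign-flip test per metric (and per soil variable); (5) Mantel
#' tests between facets within each category; (6) Blomberg's K per
#' quantitative trait; (7) Euclidean distances for pruned soil variables
#' and a long-format pair table ready for external SEM software.
#'
#' Deterministic for a fixed input and `config$seed`.
#'
#' @param input A `road_sim`, a `sim_config`, or a named list of paths
#'   (`tree`, `community`, `traits`, `trait_types`, `soil`); `trait_types`
#'   is a CSV with columns `trait`, `type`.
#' @param config A [run_config()].
#' @return Object of class `study_report` with tidy tibbles `comparison`,
#'   `soil_comparison`, `mantel`, `signal`, `plot_means`, `pairs`, the
#'   facet matrices, the functional dendrogram and the retained variable
#'   lists.
#' @export
run_study <- function(input, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "': ", conditionMessage(e)))
    })
  }

  sim <- NULL
  if (inherits(input, "sim_config")) input <- simulate_study(input)
  if (inherits(input, "road_sim")) {
    sim <- input
    tree <- sim$tree; traits <- sim$traits; comm <- sim$comm; soil <- sim$soil
  } else if (is.list(input)) {
    need <- c("tree", "community", "traits", "trait_types", "soil")
    if (!all(need %in% names(input))) {
      abort(paste0("file input must name paths: ", paste(need, collapse = ", ")))
    }
    tree <- stage("read", read_newick(input$tree))
    comm <- stage("read", read_community_matrix(input$community))
    tt <- stage("read", readr::read_csv(input$trait_types, show_col_types = FALSE,
                                        progress = FALSE))
    traits <- stage("read", read_trait_table(input$traits,
                                             setNames(tt$type, tt$trait)))
    soil <- stage("read", read_soil_table(input$soil))
  } else {
    abort("input must be a road_sim, a sim_config, or a list of file paths")
  }
  stage("validate", check_paired_design(comm))
  missing_sp <- setdiff(colnames(comm$occupancy), traits$data$species_id)
  if (length(missing_sp)) {
    abort(paste0("stage 'validate': species absent from trait table: ",
                 paste(head(missing_sp, 5), collapse = ", ")))
  }

  # functional space
  quant <- names(traits$types)[traits$types == "quantitative"]
  categ <- names(traits$types)[traits$types == "categorical"]
  retained_traits <- stage("trait_pruning", prune_correlated(
    traits, threshold = config$prune_threshold, method = config$cor_method,
    columns = quant
  ))
  kept <- c(retained_traits, categ)
  func_traits <- trait_table(traits$data[c("species_id", kept)],
                             traits$types[kept])
  gower <- stage("gower", gower_distance(func_traits))
  dendro <- stage("upgma", upgma(gower))

  # beta facets
  facets <- list(
    taxonomic = stage("beta_taxonomic", beta_matrix(comm, "taxonomic")),
    functional = stage("beta_functional", beta_matrix(comm, "functional",
                                                      tree = dendro)),
    phylogenetic = stage("beta_phylogenetic", beta_matrix(
      comm, "phylogenetic", tree = tree,
      exclude_shared_mpd = config$exclude_shared_mpd
    ))
  )

  # per-plot means for every metric
  metrics <- tidyr::expand_grid(
    facet = names(facets),
    component = c("beta_total", "beta_repl", "beta_rich")
  )
  metrics <- dplyr::bind_rows(metrics,
                              tibble(facet = "phylogenetic", component = "bwpbd"))
  metrics$metric <- ifelse(
    metrics$component == "bwpbd", "bwpbd",
    paste0(metrics$component, "_", facet_suffix[metrics$facet])
  )
  plot_means <- stage("plot_means", purrr::map2_dfr(
    metrics$facet, metrics$component,
    function(f, co) {
      plotwise_mean_beta(facets[[f]], co) |>
        dplyr::mutate(
          facet = f,
          metric = ifelse(co == "bwpbd", "bwpbd",
                          paste0(co, "_", facet_suffix[f]))
        )
    }
  ))

  # roadside vs interior comparison, paired by site
  comparison <- stage("comparison", purrr::imap_dfr(
    split(plot_means, plot_means$metric),
    function(pm, metric_name) {
      i <- comparison_seed_index(metric_name, metrics$metric)
      wide <- tidyr::pivot_wider(pm[c("site_id", "category", "value")],
                                 names_from = "category", values_from = "value")
      cmp <- percent_change(
        setNames(wide$interior, wide$site_id),
        setNames(wide$roadside, wide$site_id),
        n_perm = config$n_perm_signflip, seed = config$seed + 100L + i
      )
      dplyr::bind_cols(tibble(metric = metric_name), glance(cmp))
    }
  ))
  comparison <- comparison[match(metrics$metric, comparison$metric), ]

  # soil comparison (same paired design, per variable)
  soil_vars <- setdiff(names(soil), "plot_id")
  soil_by_plot <- dplyr::left_join(comm$meta, soil, by = "plot_id")
  soil_comparison <- stage("soil_comparison", purrr::imap_dfr(
    setNames(soil_vars, soil_vars),
    function(v, nm) {
      wide <- tidyr::pivot_wider(
        soil_by_plot[c("site_id", "category", v)],
        names_from = "category", values_from = dplyr::all_of(v)
      )
      diffs <- wide$interior - wide$roadside
      p <- paired_signflip_test(diffs, n_perm = config$n_perm_signflip,
                                seed = config$seed + 200L + match(nm, soil_vars))
      tibble(variable = nm, interior_mean = mean(wide$interior),
             roadside_mean = mean(wide$roadside),
             mean_difference = mean(diffs), p.value = p)
    }
  ))

  # Mantel tests between facets
  mantel <- stage("mantel", run_mantel_table(facets, config))

  # phylogenetic signal per quantitative trait
  signal <- stage("signal", purrr::imap_dfr(
    setNames(quant, quant),
    function(tr, nm) {
      vals <- setNames(traits$data[[tr]], traits$data$species_id)
      vals <- vals[!is.na(vals)]
      keep <- intersect(tree$tip.label, names(vals))
      if (length(keep) < 4 || var(vals[keep]) == 0) {
        return(tibble(trait = nm, K = NA_real_, p.value = NA_real_,
                      n_species = length(keep)))
      }
      sub <- if (length(keep) < length(tree$tip.label)) {
        ape::keep.tip(tree, keep)
      } else tree
      res <- blomberg_k(sub, vals[keep], n_perm = config$n_perm_signal,
                        seed = config$seed + 300L + match(nm, quant))
      tibble(trait = nm, K = res$k, p.value = res$p, n_species = length(keep))
    }
  ))

  # soil distances + SEM-ready pair table
  retained_soil <- stage("soil_pruning", prune_correlated(
    soil, threshold = config$prune_threshold, method = config$cor_method
  ))
  pairs <- stage("pairs_export", build_pair_table(facets, soil, retained_soil,
                                                  comm$meta))

  structure(
    list(comparison = comparison, soil_comparison = soil_comparison,
         mantel = mantel, signal = signal, plot_means = plot_means,
         pairs = pairs, facets = facets, dendrogram = dendro, tree = tree,
         gower = gower, retained_traits = retained_traits,
         retained_soil = retained_soil, meta = comm$meta, config = config,
         sim = sim),
    class = "study_report"
  )
}

comparison_seed_index <- function(metric, all_metrics) match(metric, sort(all_metrics))

run_mantel_table <- function(facets, config) {
  combos <- dplyr::bind_rows(
    tidyr::expand_grid(
      facet_1 = c("taxonomic", "taxonomic", "functional"),
      component = c("beta_total", "beta_repl", "beta_rich")
    ) |>
      dplyr::mutate(facet_2 = rep(c("functional", "phylogenetic", "phylogenetic"),
                                  each = 3)),
    tibble(facet_1 = c("taxonomic", "functional", "phylogenetic"),
           component = "beta_total", facet_2 = "bwpbd")
  )
  cats <- if (config$mantel_pooled) "pooled" else c("roadside", "interior")
  purrr::map_dfr(cats, function(cat) {
    purrr::pmap_dfr(combos, function(facet_1, component, facet_2) {
      i <- which(combos$facet_1 == facet_1 & combos$component == component &
                   combos$facet_2 == facet_2)
      get_mat <- function(f, comp, category) {
        if (f == "bwpbd") category_matrix(facets$phylogenetic, "bwpbd", category)
        else category_matrix(facets[[f]], comp, category)
      }
      seed_i <- config$seed + 400L + i +
        50L * match(cat, c("roadside", "interior", "pooled"))
      if (cat == "pooled") {
        res <- mantel_pooled_test(
          lapply(c("roadside", "interior"), function(cc) get_mat(facet_1, component, cc)),
          lapply(c("roadside", "interior"), function(cc) get_mat(facet_2, component, cc)),
          n_perm = config$n_perm_mantel, seed = seed_i
        )
      } else {
        res <- mantel_test(get_mat(facet_1, component, cat),
                           get_mat(facet_2, component, cat),
                           n_perm = config$n_perm_mantel, seed = seed_i)
      }
      tibble(category = cat, component = component,
             facet_1 = facet_1, facet_2 = facet_2,
             r = res$r, p.value = res$p, n_pairs = res$n_pairs)
    })
  })
}

# pooled variant: concatenate the two categories' pair vectors; each
# permutation shuffles plots within each category independently
mantel_pooled_test <- function(mats1, mats2, n_perm = 999, seed = NULL) {
  v1 <- unlist(lapply(mats1, lower_triangle))
  v2 <- unlist(lapply(mats2, lower_triangle))
  if (sd(v1) == 0 || sd(v2) == 0) abort("constant distance vector")
  r_obs <- cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    v2p <- unlist(lapply(mats2, function(M) {
      p <- sample.int(nrow(M))
      lower_triangle(M[p, p])
    }))
    cor(v1, v2p)
  }, numeric(1))
  list(r = r_obs, p = (sum(r_perm >= r_obs) + 1) / (n_perm + 1),
       n_pairs = length(v1), n_perm = n_perm)
}

build_pair_table <- function(facets, soil, retained_soil, meta) {
  base <- tidy.facet_beta(facets$taxonomic)
  names(base)[names(base) %in% c("beta_total", "beta_repl", "beta_rich")] <-
    paste0(c("beta_total", "beta_repl", "beta_rich"), "_tax")
  for (f in c("functional", "phylogenetic")) {
    td <- tidy.facet_beta(facets[[f]])
    comps <- setdiff(names(td), c("plot_i", "plot_j", "category"))
    for (co in comps) {
      nm <- if (co == "bwpbd") "bwpbd" else paste0(co, "_", facet_suffix[f])
      base[[nm]] <- td[[co]]
    }
  }
  soil_ord <- soil[match(meta$plot_id, soil$plot_id), ]
  for (v in retained_soil) {
    D <- euclidean_distance_matrix(soil_ord, v)
    vals <- purrr::map2_dbl(base$plot_i, base$plot_j, function(i, j) D[i, j])
    base[[paste0("soil_", v)]] <- vals
  }
  base
}

#' @export
print.study_report <- function(x, ...) {
  n_cat <- table(x$meta$category)
  cat("<study_report> ", nrow(x$meta), " plots (",
      paste(sprintf("%d %s", n_cat, names(n_cat)), collapse = ", "), "), ",
      nrow(x$pairs), " within-category pairs\n", sep = "")
  cat("Roadside-vs-interior comparison (percent change, + = decrease at roadside):\n")
  print(as.data.frame(x$comparison[c("metric", "interior_mean", "roadside_mean",
                                     "percent_change", "p.value")]),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method tidy study_report
tidy.study_report <- function(x, ...) x$comparison

#' @export
#' @method glance study_report
glance.study_report <- function(x, ...) {
  tibble(
    n_plots = nrow(x$meta),
    n_sites = length(unique(x$meta$site_id)),
    n_species = length(x$tree$tip.label),
    n_pairs = nrow(x$pairs),
    n_traits_retained = length(x$retained_traits),
    n_soil_retained = length(x$retained_soil),
    seed = x$config$seed
  )
}

#' Write all study outputs as CSV files
#'
#' Emits `comparison.csv`, `soil_comparison.csv`, `mantel.csv`,
#' `signal.csv`, `plot_means.csv`, per-category pair tables
#' `pairs_<category>.csv` (the export consumed by external SEM software),
#' square matrices `beta_<facet>_<component>_<category>.csv`, and
#' `run_info.csv` with the seed and configuration. Re-running the same
#' input and seed reproduces every file byte-identically.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of paths, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p, progress = FALSE)
    paths <<- c(paths, p)
  }
  wr(report$comparison, "comparison.csv")
  wr(report$soil_comparison, "soil_comparison.csv")
  wr(report$mantel, "mantel.csv")
  wr(report$signal, "signal.csv")
  wr(report$plot_means, "plot_means.csv")
  for (cat in unique(report$pairs$category)) {
    wr(report$pairs[report$pairs$category == cat, ],
       paste0("pairs_", cat, ".csv"))
  }
  for (f in names(report$facets)) {
    for (co in names(report$facets[[f]]$matrices)) {
      for (cat in c("roadside", "interior")) {
        M <- category_matrix(report$facets[[f]], co, cat)
        df <- dplyr::bind_cols(tibble(plot_id = rownames(M)), as_tibble(M))
        wr(df, paste0("beta_", facet_suffix[f], "_", co, "_", cat, ".csv"))
      }
    }
  }
  cfg <- report$config
  wr(tibble(key = names(cfg)[!vapply(cfg, is.list, logical(1))],
            value = vapply(cfg[!vapply(cfg, is.list, logical(1))],
                           function(v) paste(format(v), collapse = ";"),
                           character(1))),
     "run_info.csv")
  invisible(paths)
}
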