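#' Shared/unique species components of a plot pair
#'
#' The (a, b, c) decomposition for the taxonomic facet: `a` species shared by
#' both communities, `b` unique to the first, `c` unique to the second.
#'
#' @param comm1,comm2 Nonempty character vectors of species ids (treated as
#'   sets).
#' @return A tibble with one row and columns `a`, `b`, `c`.
#' @examples
#' species_abc(c("A", "B"), c("B", "C")) # a = b = c = 1
#' @export
species_abc <- function(comm1, comm2) {
  comm1 <- unique(comm1)
  comm2 <- unique(comm2)
  if (!length(comm1) || !length(comm2)) abort("communities must be nonempty")
  a <- length(intersect(comm1, comm2))
  tibble(a = a, b = length(comm1) - a, c = length(comm2) - a)
}

#' Root-to-tip branch incidence of a tree
#'
#' For every edge, which tips lie below it. The branch set of a community is
#' the union of root-to-tip paths of its members; this incidence matrix turns
#' the branch-set (a, b, c) computation into boolean matrix algebra.
#'
#' @param tree A `phylo` tree.
#' @return List with `incidence` (edges x tips logical matrix, columns named
#'   by tip label) and `lengths` (edge lengths, aligned with rows).
#' @export
branch_incidence <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- validate_tree(tree)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- matrix(FALSE, n_node, n_tip)
  below[cbind(seq_len(n_tip), seq_len(n_tip))] <- TRUE
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1]
    chi <- po$edge[e, 2]
    below[par, ] <- below[par, ] | below[chi, ]
  }
  inc <- below[tree$edge[, 2], , drop = FALSE]
  colnames(inc) <- tree$tip.label
  list(incidence = inc, lengths = tree$edge.length)
}

#' Shared/unique branch-length components of a plot pair
#'
#' The length-weighted (a, b, c) decomposition on a tree: each community's
#' branch set is the union of edges on the root-to-tip paths of its members;
#' `a` is the total length of edges in both sets, `b` and `c` the total
#' lengths unique to each side. On a unit-branch star tree this reduces
#' exactly to [species_abc()]. Branch sets are rooted at the global root of
#' the supplied tree; set `mrca_rescope = TRUE` to instead drop edges
#' ancestral to the pair's combined most recent common ancestor.
#'
#' @param comm1,comm2 Nonempty character vectors of tip labels.
#' @param tree A `phylo` tree containing every named species as a tip.
#' @param incidence Optional precomputed [branch_incidence()] for `tree`
#'   (recomputed when `NULL`).
#' @param mrca_rescope If `TRUE`, restrict both branch sets to edges below
#'   the MRCA of the union of the two communities. Default `FALSE`.
#' @return A tibble with one row and columns `a`, `b`, `c` (branch lengths).
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' branch_abc(c("A", "B"), "C", tr) # a = 0, b = 3, c = 2
#' @export
branch_abc <- function(comm1, comm2, tree, incidence = NULL,
                       mrca_rescope = FALSE) {
  comm1 <- unique(comm1)
  comm2 <- unique(comm2)
  if (!length(comm1) || !length(comm2)) abort("communities must be nonempty")
  absent <- setdiff(c(comm1, comm2), tree$tip.label)
  if (length(absent)) {
    abort(paste0("species missing from tree: ", paste(absent, collapse = ", ")))
  }
  bi <- incidence %||% branch_incidence(tree)
  in1 <- rowSums(bi$incidence[, comm1, drop = FALSE]) > 0
  in2 <- rowSums(bi$incidence[, comm2, drop = FALSE]) > 0
  keep <- rep(TRUE, length(in1))
  if (mrca_rescope) {
    both <- union(comm1, comm2)
    if (length(both) > 1) {
      anc <- ape::getMRCA(tree, both)
      # keep only edges whose tip set is a subset of the MRCA clade
      clade_tips <- if (anc <= length(tree$tip.label)) {
        tree$tip.label[anc]
      } else {
        tree$tip.label[unlist(phangorn_desc(tree, anc))]
      }
      # strictly below the MRCA: the clade's stem edge is excluded
      keep <- rowSums(bi$incidence[, setdiff(tree$tip.label, clade_tips),
                                   drop = FALSE]) == 0 & tree$edge[, 2] != anc
    } else {
      # single shared tip: its terminal edge is the whole scoped branch set
      keep <- bi$incidence[, both] & rowSums(bi$incidence) == 1
    }
  }
  len <- bi$lengths * keep
  tibble(
    a = sum(len[in1 & in2]),
    b = sum(len[in1 & !in2]),
    c = sum(len[!in1 & in2])
  )
}

# tips descending from an internal node, by edge traversal (no extra deps)
phangorn_desc <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  todo <- node
  tips <- integer(0)
  while (length(todo)) {
    cur <- todo[1]
    todo <- todo[-1]
    kids <- tree$edge[tree$edge[, 1] == cur, 2]
    tips <- c(tips, kids[kids <= n_tip])
    todo <- c(todo, kids[kids > n_tip])
  }
  tips
}

#' Jaccard partition of beta diversity into replacement and richness difference
#'
#' The Podani-family decomposition of total Jaccard dissimilarity:
#' \deqn{\beta_{total} = (b+c)/(a+b+c)}
#' \deqn{\beta_{repl} = 2\min(b,c)/(a+b+c)}
#' \deqn{\beta_{rich} = |b-c|/(a+b+c)}
#' so that beta_total = beta_repl + beta_rich exactly. The same formulas
#' apply to species counts (taxonomic), functional-dendrogram branch lengths
#' (functional) and phylogeny branch lengths (tip-weighted phylogenetic).
#'
#' @param a Either a numeric vector of shared amounts, or a data frame with
#'   columns `a`, `b`, `c` (as returned by [species_abc()]/[branch_abc()]).
#' @param b,c Numeric vectors (recycled with `a`) when `a` is numeric.
#' @return Tibble with columns `beta_total`, `beta_repl`, `beta_rich`, one
#'   row per input triple.
#' @examples
#' jaccard_partition(1, 1, 1) # 2/3, 2/3, 0
#' jaccard_partition(species_abc(c("A", "B"), c("B", "C")))
#' @export
jaccard_partition <- function(a, b = NULL, c = NULL) {
  if (is.data.frame(a)) {
    abc <- a
    if (!all(c("a", "b", "c") %in% names(abc))) {
      abort("data frame input must have columns a, b, c")
    }
    a <- abc$a; b <- abc$b; c <- abc$c
  }
  if (is.null(b) || is.null(c)) abort("supply b and c (or a data frame with a, b, c)")
  if (any(a < 0 | b < 0 | c < 0)) abort("a, b, c must be nonnegative")
  tot <- a + b + c
  if (any(tot <= 0)) abort("a + b + c must be positive (empty comparison is undefined)")
  tibble(
    beta_total = (b + c) / tot,
    beta_repl = 2 * pmin(b, c) / tot,
    beta_rich = abs(b - c) / tot
  )
}

#' Between-community mean pairwise phylogenetic distance (basal-weighted PBD)
#'
#' The mean patristic distance over all ordered cross pairs of species, one
#' drawn from each community. Dominated by deep branches near the root, it is
#' the basal-weighted complement to the branch-set Jaccard partition, which
#' is tip-weighted. Species shared by both communities enter as zero-distance
#' pairs by default; set `exclude_shared = TRUE` to average over
#' distinct-species pairs only.
#'
#' @param comm1,comm2 Nonempty character vectors of tip labels.
#' @param tree A `phylo` tree (used when `patristic` is `NULL`).
#' @param patristic Optional precomputed patristic matrix
#'   (`ape::cophenetic.phylo(tree)`).
#' @param exclude_shared Drop same-species (zero) pairs from the average.
#' @return A single nonnegative number.
#' @examples
#' star <- read_newick("(A:1,B:1,C:1);")
#' mpd_between("A", "B", star) # 2
#' @export
mpd_between <- function(comm1, comm2, tree = NULL, patristic = NULL,
                        exclude_shared = FALSE) {
  comm1 <- unique(comm1)
  comm2 <- unique(comm2)
  if (!length(comm1) || !length(comm2)) abort("communities must be nonempty")
  if (is.null(patristic)) {
    if (is.null(tree)) abort("supply a tree or a patristic matrix")
    absent <- setdiff(c(comm1, comm2), tree$tip.label)
    if (length(absent)) {
      abort(paste0("species missing from tree: ", paste(absent, collapse = ", ")))
    }
    patristic <- ape::cophenetic.phylo(tree)
  }
  M <- patristic[comm1, comm2, drop = FALSE]
  if (exclude_shared) {
    same <- outer(comm1, comm2, "==")
    if (all(same)) abort("no distinct-species pairs to average over")
    return(mean(M[!same]))
  }
  mean(M)
}

#' Pairwise beta-diversity matrices for one facet
#'
#' Computes the Jaccard partition for every unordered pair of plots within
#' the same category (roadside with roadside, interior with interior);
#' cross-category cells are `NA` because the design never compares across
#' categories. The taxonomic facet counts species; the functional and
#' phylogenetic facets measure branch lengths on the supplied dendrogram /
#' phylogeny via [branch_abc()]. The phylogenetic facet additionally carries
#' the basal-weighted between-community MPD matrix.
#'
#' @param comm A [community_matrix()].
#' @param facet One of `"taxonomic"`, `"functional"`, `"phylogenetic"`.
#' @param tree `phylo` tree; required for the functional and phylogenetic
#'   facets (the functional dendrogram from [upgma()], or the phylogeny).
#' @param exclude_shared_mpd Passed to [mpd_between()] for the bwPBD matrix.
#' @return An object of class `facet_beta`: list with `facet`, `matrices`
#'   (named list of plot x plot matrices `beta_total`, `beta_repl`,
#'   `beta_rich`, plus `bwpbd` for the phylogenetic facet) and `meta` (plot
#'   metadata tibble).
#' @export
beta_matrix <- function(comm, facet = c("taxonomic", "functional", "phylogenetic"),
                        tree = NULL, exclude_shared_mpd = FALSE) {
  facet <- match.arg(facet)
  stopifnot(inherits(comm, "community_matrix"))
  X <- comm$occupancy
  n <- nrow(X)
  if (facet != "taxonomic") {
    if (is.null(tree)) abort(paste0("facet '", facet, "' requires a tree"))
    absent <- setdiff(colnames(X), tree$tip.label)
    if (length(absent)) {
      abort(paste0("species missing from tree: ",
                   paste(head(absent, 5), collapse = ", "),
                   if (length(absent) > 5) " ..."))
    }
  }

  if (facet == "taxonomic") {
    A <- X %*% t(X)                       # shared species counts
    tot <- rowSums(X)
  } else {
    bi <- branch_incidence(tree)
    inc <- bi$incidence[, colnames(X), drop = FALSE]   # edges x species
    P <- (X %*% t(inc)) > 0                            # plots x edges
    Pl <- P * matrix(bi$lengths, n, length(bi$lengths), byrow = TRUE)
    A <- Pl %*% t(P)                      # shared branch length
    tot <- rowSums(Pl)
  }
  B <- matrix(tot, n, n) - A              # unique to row plot
  C <- t(B)                               # unique to column plot
  S <- A + B + C
  beta_total <- (B + C) / S
  beta_repl <- 2 * pmin(B, C) / S
  beta_rich <- abs(B - C) / S

  same_cat <- outer(comm$meta$category, comm$meta$category, "==")
  mask <- function(M) {
    M[!same_cat] <- NA_real_
    diag(M) <- 0
    dimnames(M) <- list(rownames(X), rownames(X))
    M
  }
  matrices <- list(
    beta_total = mask(beta_total),
    beta_repl = mask(beta_repl),
    beta_rich = mask(beta_rich)
  )
  if (facet == "phylogenetic") {
    Dp <- ape::cophenetic.phylo(tree)[colnames(X), colnames(X)]
    M <- X %*% Dp %*% t(X)
    npairs <- outer(rowSums(X), rowSums(X))
    if (exclude_shared_mpd) npairs <- npairs - A   # shared species = zero pairs
    bw <- M / npairs
    bw[npairs <= 0] <- NA_real_
    matrices$bwpbd <- mask(bw)
  }
  structure(
    list(facet = facet, matrices = matrices, meta = comm$meta),
    class = "facet_beta"
  )
}

#' @export
print.facet_beta <- function(x, ...) {
  cat("<facet_beta> facet: ", x$facet, "; ", nrow(x$meta), " plots; components: ",
      paste(names(x$matrices), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract the within-category submatrix of a beta component
#'
#' @param facet_result A [beta_matrix()] result.
#' @param component One of `"beta_total"`, `"beta_repl"`, `"beta_rich"`,
#'   `"bwpbd"`.
#' @param category `"roadside"` or `"interior"`.
#' @return The square plot x plot matrix restricted to the category's plots.
#' @export
category_matrix <- function(facet_result, component, category) {
  stopifnot(inherits(facet_result, "facet_beta"))
  if (!component %in% names(facet_result$matrices)) {
    abort(paste0("unknown component '", component, "' for facet '",
                 facet_result$facet, "'"))
  }
  keep <- facet_result$meta$plot_id[facet_result$meta$category == category]
  if (!length(keep)) abort(paste0("no plots in category '", category, "'"))
  facet_result$matrices[[component]][keep, keep, drop = FALSE]
}

#' Tidy a facet_beta object into a long pair table
#'
#' One row per within-category unordered plot pair, in the fixed row-major
#' lower-triangle order used throughout (so vectors align across facets).
#'
#' @param x A `facet_beta` object.
#' @param ... Unused.
#' @return Tibble with `plot_i`, `plot_j`, `category` and one column per
#'   component.
#' @export
#' @method tidy facet_beta
tidy.facet_beta <- function(x, ...) {
  purrr::map_dfr(c("roadside", "interior"), function(cat) {
    ids <- x$meta$plot_id[x$meta$category == cat]
    if (length(ids) < 2) return(NULL)
    pairs <- lower_triangle_pairs(ids)
    vals <- purrr::map(x$matrices, function(M) {
      lower_triangle(M[ids, ids, drop = FALSE])
    })
    dplyr::bind_cols(
      tibble(plot_i = pairs$i, plot_j = pairs$j, category = cat),
      as_tibble(vals)
    )
  })
}

#' Single-variable Euclidean (absolute-difference) distances among plots
#'
#' For one soil variable, `d(p, q) = |x_p - x_q|`; when plot metadata is
#' supplied, cross-category cells are `NA` to match the within-category
#' design of the beta matrices.
#'
#' @param soil Soil tibble (`plot_id` + numeric columns).
#' @param variable Column name.
#' @param meta Optional plot metadata with `plot_id` and `category`.
#' @return Symmetric plot x plot matrix.
#' @export
euclidean_distance_matrix <- function(soil, variable, meta = NULL) {
  soil <- validate_soil_table(soil)
  if (!variable %in% names(soil)) {
    abort(paste0("unknown soil variable '", variable, "'"))
  }
  x <- soil[[variable]]
  D <- abs(outer(x, x, "-"))
  dimnames(D) <- list(soil$plot_id, soil$plot_id)
  if (!is.null(meta)) {
    cat_of <- setNames(meta$category, meta$plot_id)[soil$plot_id]
    same <- outer(cat_of, cat_of, "==")
    D[!same] <- NA_real_
    diag(D) <- 0
  }
  D
}
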