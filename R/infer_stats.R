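#' Below-diagonal entries of a distance matrix, in fixed order
#'
#' Row-major over (row > col): row 2 gives d21, row 3 gives d31, d32, and so
#' on. This single fixed order is used everywhere a matrix is vectorized, so
#' the pair vectors of different facets and soil variables stay aligned (a
#' 38-plot category yields 703 entries).
#'
#' @param D Square matrix.
#' @return Numeric vector of length n(n-1)/2.
#' @export
lower_triangle <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("lower_triangle needs a square matrix")
  t(D)[upper.tri(D)]
}

# pair labels matching lower_triangle() order
lower_triangle_pairs <- function(ids) {
  n <- length(ids)
  # row-major (row > col): rows 2..n, each preceded by its cols 1..row-1
  row <- unlist(lapply(seq_len(n)[-1], function(r) rep(r, r - 1L)))
  col <- unlist(lapply(seq_len(n)[-1], function(r) seq_len(r - 1L)))
  list(i = ids[row], j = ids[col])
}

#' Simple Mantel test between two distance matrices
#'
#' Pearson correlation of the two lower-triangle vectors, with significance
#' from jointly permuting rows and columns of the second matrix (the standard
#' simple Mantel null). One-tailed (greater) with the add-one convention:
#' p = (#\{r_perm >= r_obs\} + 1) / (n_perm + 1), so p >= 1/(n_perm + 1).
#'
#' @param D1,D2 Square distance matrices with identical id ordering (same
#'   dimnames, no missing cells).
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `mantel_result` with fields `r`, `p`, `n_perm`,
#'   `n_pairs`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = NULL) {
  if (!is.matrix(D1) || !is.matrix(D2) || !all(dim(D1) == dim(D2))) {
    abort("D1 and D2 must be square matrices of equal size")
  }
  if (!is.null(dimnames(D1)) && !is.null(dimnames(D2)) &&
      !identical(rownames(D1), rownames(D2))) {
    abort("D1 and D2 must share the same id ordering")
  }
  if (n_perm < 1) abort("n_perm must be >= 1")
  v1 <- lower_triangle(D1)
  v2 <- lower_triangle(D2)
  if (anyNA(v1) || anyNA(v2)) abort("distance matrices must not contain NA")
  if (sd(v1) == 0 || sd(v2) == 0) abort("constant distance vector: correlation undefined")
  r_obs <- cor(v1, v2)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(D2)
  r_perm <- vapply(seq_len(n_perm), function(k) {
    p <- sample.int(n)
    cor(v1, lower_triangle(D2[p, p]))
  }, numeric(1))
  p_val <- (sum(r_perm >= r_obs) + 1) / (n_perm + 1)
  structure(
    list(r = r_obs, p = p_val, n_perm = n_perm, n_pairs = length(v1)),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%d permutations, %d pairs)\n",
              x$r, x$p, x$n_perm, x$n_pairs))
  invisible(x)
}

#' @export
#' @method tidy mantel_result
tidy.mantel_result <- function(x, ...) {
  tibble(r = x$r, p.value = x$p, n_perm = x$n_perm, n_pairs = x$n_pairs)
}

#' Blomberg's K phylogenetic signal with a permutation test
#'
#' K compares the observed ratio of tip-level variance (around the
#' phylogenetically corrected mean) to the phylogenetically expected variance
#' against the same ratio expected under Brownian motion on the given tree:
#' \deqn{K = \frac{(MSE_0/MSE)_{obs}}{(\mathrm{tr}(V) - n/\mathbf{1}'V^{-1}\mathbf{1})/(n-1)}}
#' where V is the tree's variance-covariance matrix. K has expectation 1
#' under Brownian motion and falls toward 0 when trait values are independent
#' of the phylogeny. Significance comes from shuffling trait values across
#' tips: p = (#\{K_perm >= K_obs\} + 1)/(n_perm + 1).
#'
#' @param tree `phylo` tree with positive branch lengths, >= 4 tips.
#' @param trait Named numeric vector covering every tip.
#' @param n_perm Number of tip shuffles (default 999); 0 skips the test.
#' @param seed Optional integer seed.
#' @return Object of class `signal_result` with fields `k`, `p`, `n_perm`.
#' @export
blomberg_k <- function(tree, trait, n_perm = 999, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n < 4) abort("blomberg_k needs at least 4 tips")
  if (is.null(names(trait)) || !all(tree$tip.label %in% names(trait))) {
    abort("trait must be named and cover every tip")
  }
  x <- as.numeric(trait[tree$tip.label])
  if (anyNA(x)) abort("trait has missing values on tree tips")
  if (var(x) == 0) abort("zero-variance trait: K undefined")
  V <- ape::vcv(tree)
  Vinv <- tryCatch(solve(V), error = function(e) {
    abort("tree variance-covariance matrix is singular (zero-length terminal branches?)")
  })
  ones <- rep(1, n)
  sum_vinv <- sum(Vinv)
  vinv_rowsum <- Vinv %*% ones
  expected <- (sum(diag(V)) - n / sum_vinv) / (n - 1)

  k_of <- function(xx) {
    ahat <- sum(vinv_rowsum * xx) / sum_vinv
    dev <- xx - ahat
    mse0 <- sum(dev^2) / (n - 1)
    mse <- drop(crossprod(dev, Vinv %*% dev)) / (n - 1)
    (mse0 / mse) / expected
  }
  k_obs <- k_of(x)
  p_val <- NA_real_
  if (n_perm >= 1) {
    if (!is.null(seed)) set.seed(seed)
    # all shuffles at once: K depends on x only through quadratic forms
    P <- vapply(seq_len(n_perm), function(k) sample(x), numeric(n))
    ahat <- drop(crossprod(P, vinv_rowsum)) / sum_vinv
    Dev <- P - matrix(ahat, n, n_perm, byrow = TRUE)
    mse0 <- colSums(Dev^2) / (n - 1)
    mse <- colSums(Dev * (Vinv %*% Dev)) / (n - 1)
    k_perm <- (mse0 / mse) / expected
    p_val <- (sum(k_perm >= k_obs) + 1) / (n_perm + 1)
  }
  structure(list(k = k_obs, p = p_val, n_perm = n_perm), class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Blomberg's K = %.4f, p = %.4g (%d permutations)\n",
              x$k, x$p, x$n_perm))
  invisible(x)
}

#' @export
#' @method tidy signal_result
tidy.signal_result <- function(x, ...) {
  tibble(K = x$k, p.value = x$p, n_perm = x$n_perm)
}

#' Per-plot mean beta diversity
#'
#' For each plot, the mean of the chosen component over all within-category
#' pairs that include the plot (n_category - 1 pairs each). These per-plot
#' means are the unit of the roadside-vs-interior comparison.
#'
#' @param facet_result A [beta_matrix()] result.
#' @param component One of the result's components (`"beta_total"`,
#'   `"beta_repl"`, `"beta_rich"`, `"bwpbd"`).
#' @return Tibble with `plot_id`, `site_id`, `road_id`, `category`,
#'   `component`, `value`.
#' @export
plotwise_mean_beta <- function(facet_result, component = "beta_total") {
  stopifnot(inherits(facet_result, "facet_beta"))
  if (!component %in% names(facet_result$matrices)) {
    abort(paste0("unknown component '", component, "'"))
  }
  meta <- facet_result$meta
  out <- purrr::map_dfr(unique(meta$category), function(cat) {
    ids <- meta$plot_id[meta$category == cat]
    if (length(ids) < 2) {
      abort(paste0("category '", cat, "' has fewer than 2 plots"))
    }
    M <- facet_result$matrices[[component]][ids, ids, drop = FALSE]
    vals <- (rowSums(M) - diag(M)) / (length(ids) - 1)
    tibble(plot_id = ids, value = unname(vals))
  })
  dplyr::left_join(meta, out, by = "plot_id") |>
    dplyr::mutate(component = component, .before = "value")
}

#' Roadside-vs-interior comparison of per-plot means
#'
#' Pairs per-plot mean beta values by site, reports the percent change
#' relative to the interior mean (positive = lower values at the roadside,
#' i.e. homogenization) and a paired sign-flip permutation p-value for the
#' mean site difference.
#'
#' @param interior,roadside Numeric vectors of per-plot means, paired by
#'   site (same order; names, when present on both, must agree).
#' @param n_perm Sign-flip permutations for the p-value (default 9999).
#' @param seed Optional integer seed.
#' @return Object of class `category_comparison` with per-site differences
#'   and summary fields; see [glance.category_comparison()].
#' @examples
#' cmp <- percent_change(rep(0.5, 6), rep(0.45, 6), n_perm = 99, seed = 1)
#' glance(cmp)$percent_change # 10
#' @export
percent_change <- function(interior, roadside, n_perm = 9999, seed = NULL) {
  if (length(interior) != length(roadside)) {
    abort("interior and roadside vectors must have equal length (paired by site)")
  }
  if (!is.null(names(interior)) && !is.null(names(roadside)) &&
      !identical(names(interior), names(roadside))) {
    abort("site names of the two vectors disagree")
  }
  m_int <- mean(interior)
  m_road <- mean(roadside)
  if (m_int == 0) abort("interior mean is 0: percent change undefined")
  diffs <- interior - roadside
  p_val <- paired_signflip_test(diffs, n_perm = n_perm, seed = seed)
  structure(
    list(
      interior_mean = m_int,
      roadside_mean = m_road,
      mean_difference = m_int - m_road,
      percent_change = 100 * (m_int - m_road) / m_int,
      differences = diffs,
      p = p_val,
      n_perm = n_perm
    ),
    class = "category_comparison"
  )
}

#' @export
print.category_comparison <- function(x, ...) {
  cat(sprintf(
    "interior %.4f vs roadside %.4f: %.2f%% %s (sign-flip p = %.4g, n = %d sites)\n",
    x$interior_mean, x$roadside_mean, abs(x$percent_change),
    if (x$percent_change >= 0) "decrease at roadside" else "increase at roadside",
    x$p, length(x$differences)
  ))
  invisible(x)
}

#' Summarize a category comparison
#'
#' @param x A [percent_change()] result.
#' @param ... Unused.
#' @return One-row tibble: `interior_mean`, `roadside_mean`,
#'   `mean_difference`, `percent_change`, `p.value`, `n_sites`, `n_perm`.
#' @export
#' @method glance category_comparison
glance.category_comparison <- function(x, ...) {
  tibble(
    interior_mean = x$interior_mean, roadside_mean = x$roadside_mean,
    mean_difference = x$mean_difference, percent_change = x$percent_change,
    p.value = x$p, n_sites = length(x$differences), n_perm = x$n_perm
  )
}

#' @export
#' @method tidy category_comparison
tidy.category_comparison <- function(x, ...) {
  tibble(site = names(x$differences) %||% seq_along(x$differences),
         difference = unname(x$differences))
}

#' Paired sign-flip permutation test
#'
#' Two-sided permutation test of mean paired difference = 0: each permutation
#' flips the sign of every difference independently and the p-value is the
#' add-one tail fraction of |mean| at least as extreme as observed. A
#' deliberately assumption-light, desk-scale alternative to a mixed-model
#' category contrast for the paired design.
#'
#' @param differences Numeric vector of paired (interior - roadside)
#'   differences, length >= 5.
#' @param n_perm Number of sign flips (default 9999).
#' @param seed Optional integer seed.
#' @return The two-sided permutation p-value.
#' @export
paired_signflip_test <- function(differences, n_perm = 9999, seed = NULL) {
  if (length(differences) < 5) abort("need at least 5 paired differences")
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (all(differences == 0)) return(1)
  obs <- abs(mean(differences))
  if (!is.null(seed)) set.seed(seed)
  n <- length(differences)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  stat <- abs(colMeans(signs * differences))
  (sum(stat >= obs) + 1) / (n_perm + 1)
}
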