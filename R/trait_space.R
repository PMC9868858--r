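#' Gower distance over a mixed trait table
#'
#' Pairwise dissimilarity for mixed quantitative/categorical traits:
#' quantitative traits contribute `|x_i - x_j| / range`, with the range taken
#' over all non-missing values in the supplied table (one global functional
#' space, so every community is scored against the same yardstick);
#' categorical traits contribute 0 on a match and 1 otherwise. Traits missing
#' in either member of a pair are skipped and the sum renormalized by the
#' number of usable traits, so all distances stay in \[0, 1\].
#'
#' A quantitative trait that is constant over all species carries no
#' information; it contributes 0 for every pair and a warning is issued.
#' Note the missing-data renormalization can break the triangle inequality -
#' Gower distances here are dissimilarities, not guaranteed metrics.
#'
#' @param traits A [trait_table()] with at least 2 species and 1 trait.
#' @return Symmetric species x species matrix of dissimilarities in \[0, 1\]
#'   with zero diagonal.
#' @examples
#' tt <- trait_table(
#'   data.frame(species_id = c("s1", "s2"), h = c(2, 7), col = c("red", "blue")),
#'   c(h = "quantitative", col = "categorical")
#' )
#' gower_distance(tt) # (|2-7|/5 + 1)/2 = 1
#' @export
gower_distance <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  ids <- traits$data$species_id
  n <- length(ids)
  if (n < 2) abort("gower_distance needs at least 2 species")
  S <- matrix(0, n, n)
  W <- matrix(0, n, n)
  for (tc in names(traits$types)) {
    x <- traits$data[[tc]]
    ok <- !is.na(x)
    usable <- outer(ok, ok, "&")
    if (traits$types[[tc]] == "quantitative") {
      rng <- if (sum(ok) > 0) diff(range(x[ok])) else 0
      if (sum(ok) > 1 && rng == 0) {
        warn(paste0("constant quantitative trait '", tc,
                    "' contributes 0 to all pairs"))
        d <- matrix(0, n, n)
      } else if (rng == 0) {
        d <- matrix(0, n, n)
      } else {
        xi <- ifelse(ok, x, 0)
        d <- abs(outer(xi, xi, "-")) / rng
      }
    } else {
      xi <- ifelse(ok, x, "")
      d <- (outer(xi, xi, "!=")) * 1
    }
    S <- S + d * usable
    W <- W + usable
  }
  off <- W == 0 & upper.tri(W)
  if (any(off)) {
    idx <- which(off, arr.ind = TRUE)[1, ]
    abort(paste0("species pair with no usable traits: '", ids[idx[1]],
                 "' vs '", ids[idx[2]], "'"))
  }
  D <- S / W
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

#' Greedy correlation-based variable pruning
#'
#' Scans columns in their given order and drops a column iff its absolute
#' correlation with any already-retained column exceeds `threshold`
#' (strictly), mirroring the rho > 0.5 screen used to thin collinear soil
#' variables before downstream modelling. Deterministic by construction.
#'
#' @param data A data frame of quantitative columns, a [trait_table()]
#'   (quantitative columns only may be selected), or a soil table; a
#'   `plot_id`/`species_id` key column is ignored.
#' @param threshold Correlation magnitude above which a column is dropped;
#'   in (0, 1]. Default 0.5.
#' @param method Correlation type, `"spearman"` (default, robust to skewed
#'   traits) or `"pearson"`.
#' @param columns Optional character vector restricting / ordering the
#'   columns considered.
#' @return Character vector of retained column names, in original order.
#' @export
prune_correlated <- function(data, threshold = 0.5,
                             method = c("spearman", "pearson"),
                             columns = NULL) {
  method <- match.arg(method)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    abort("threshold must be a single value in (0, 1]")
  }
  if (inherits(data, "trait_table")) {
    cols <- columns %||% names(data$types)
    non_quant <- cols[data$types[cols] != "quantitative"]
    if (length(non_quant)) {
      abort(paste0("non-quantitative column(s) in pruning: ",
                   paste(non_quant, collapse = ", ")))
    }
    df <- data$data[cols]
  } else {
    df <- as_tibble(data)
    df <- df[setdiff(names(df), c("plot_id", "species_id"))]
    if (!is.null(columns)) df <- df[columns]
    non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
    if (length(non_num)) {
      abort(paste0("non-quantitative column(s) in pruning: ",
                   paste(non_num, collapse = ", ")))
    }
  }
  if (ncol(df) < 2) return(names(df))
  retained <- names(df)[1]
  for (cn in names(df)[-1]) {
    rho <- vapply(
      retained,
      function(rc) {
        suppressWarnings(
          cor(df[[cn]], df[[rc]], use = "pairwise.complete.obs", method = method)
        )
      },
      numeric(1)
    )
    if (!any(abs(rho) > threshold, na.rm = TRUE)) retained <- c(retained, cn)
  }
  retained
}

#' UPGMA dendrogram from a distance matrix
#'
#' Unweighted pair-group average-linkage clustering: the clusters at minimal
#' distance merge, the new node sits at half the merge distance, and
#' distances to the merged cluster update as size-weighted averages. The
#' result is an ultrametric tree (equal root-to-tip path lengths) whose
#' cophenetic distances equal the merge distances. Used to turn the Gower
#' trait distances into the functional dendrogram that the branch-set beta
#' machinery consumes.
#'
#' Clustering is delegated to [stats::hclust()] (`method = "average"`) and
#' converted with [ape::as.phylo()]; exact ties follow `hclust`'s
#' deterministic ordering.
#'
#' @param dist Symmetric distance matrix (or `dist` object), n >= 2, finite.
#' @return Ultrametric `phylo` tree with the input labels as tips.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(LETTERS[1:3], LETTERS[1:3]))
#' tr <- upgma(d)
#' ape::is.ultrametric(tr)
#' @export
upgma <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  validate_distance_matrix(dist)
  if (nrow(dist) < 2) abort("upgma needs at least 2 items")
  tree <- ape::as.phylo(hclust(as.dist(dist), method = "average"))
  tree
}

validate_distance_matrix <- function(D, tol = 1e-12) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) abort("distance matrix must be square")
  if (anyNA(D) || any(!is.finite(D))) abort("distance matrix has NA/NaN/Inf entries")
  if (any(D < 0)) abort("distance matrix has negative entries")
  if (max(abs(D - t(D))) > tol) abort("distance matrix is not symmetric")
  if (any(diag(D) != 0)) abort("distance matrix diagonal must be 0")
  invisible(D)
}
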