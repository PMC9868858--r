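# Independent naive reimplementations used as oracles. Deliberately simple,
# loop-based, and sharing no code with the package internals.

# per-pair Gower loop: ranges over all non-missing values, pairwise skip +
# renormalize
oracle_gower <- function(df, types) {
  ids <- df$species_id
  n <- length(ids)
  traits <- setdiff(names(df), "species_id")
  rng <- lapply(traits, function(tc) {
    if (types[[tc]] == "quantitative") range(df[[tc]], na.rm = TRUE) else NULL
  })
  names(rng) <- traits
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- 0
      den <- 0
      for (tc in traits) {
        xi <- df[[tc]][i]
        xj <- df[[tc]][j]
        if (is.na(xi) || is.na(xj)) next
        den <- den + 1
        if (types[[tc]] == "quantitative") {
          r <- diff(rng[[tc]])
          if (r > 0) num <- num + abs(xi - xj) / r
        } else {
          num <- num + as.numeric(xi != xj)
        }
      }
      D[i, j] <- num / den
    }
  }
  D
}

# O(n^3) UPGMA returning the cophenetic matrix (merge heights)
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  ids <- rownames(D)
  clusters <- as.list(seq_len(n))
  act <- rep(TRUE, n)
  W <- D
  coph <- matrix(0, n, n, dimnames = list(ids, ids))
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    idx <- which(act)
    for (a in idx) {
      for (b in idx) {
        if (a < b && W[a, b] < best_d) {
          best_d <- W[a, b]
          best <- c(a, b)
        }
      }
    }
    u <- best[1]
    v <- best[2]
    for (i in clusters[[u]]) for (j in clusters[[v]]) {
      coph[i, j] <- best_d
      coph[j, i] <- best_d
    }
    nu <- length(clusters[[u]])
    nv <- length(clusters[[v]])
    for (w in idx) {
      if (w == u || w == v) next
      W[u, w] <- (nu * W[u, w] + nv * W[v, w]) / (nu + nv)
      W[w, u] <- W[u, w]
    }
    clusters[[u]] <- c(clusters[[u]], clusters[[v]])
    act[v] <- FALSE
  }
  coph
}

# explicit root-to-tip edge sets via parent walking
oracle_edge_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1
  parent_edge <- integer(max(tree$edge))
  parent_node <- integer(max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent_edge[tree$edge[e, 2]] <- e
    parent_node[tree$edge[e, 2]] <- tree$edge[e, 1]
  }
  sets <- list()
  for (t in seq_len(n_tip)) {
    path <- integer(0)
    node <- t
    while (node != root) {
      path <- c(path, parent_edge[node])
      node <- parent_node[node]
    }
    sets[[tree$tip.label[t]]] <- path
  }
  sets
}

oracle_branch_abc <- function(comm1, comm2, tree) {
  sets <- oracle_edge_sets(tree)
  b1 <- unique(unlist(sets[comm1]))
  b2 <- unique(unlist(sets[comm2]))
  len <- tree$edge.length
  c(a = sum(len[intersect(b1, b2)]),
    b = sum(len[setdiff(b1, b2)]),
    c = sum(len[setdiff(b2, b1)]))
}

# patristic distance as symmetric-difference of root-path edge sets
oracle_patristic <- function(tree) {
  sets <- oracle_edge_sets(tree)
  tips <- tree$tip.label
  D <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (i in tips) {
    for (j in tips) {
      if (i == j) next
      sym <- c(setdiff(sets[[i]], sets[[j]]), setdiff(sets[[j]], sets[[i]]))
      D[i, j] <- sum(tree$edge.length[sym])
    }
  }
  D
}

oracle_mpd_between <- function(comm1, comm2, tree) {
  D <- oracle_patristic(tree)
  tot <- 0
  for (i in comm1) for (j in comm2) tot <- tot + D[i, j]
  tot / (length(comm1) * length(comm2))
}

# random helpers -------------------------------------------------------------

random_symmetric_matrix <- function(n, labels = paste0("x", seq_len(n))) {
  M <- matrix(runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(labels, labels)
  M
}

random_community_set <- function(species, min_size = 1) {
  size <- sample(seq(min_size, length(species)), 1)
  sample(species, size)
}

# unlabelled-category community for matrix-level tests
toy_community <- function(occ_list, category = NULL) {
  plots <- names(occ_list)
  species <- sort(unique(unlist(occ_list)))
  occ <- matrix(0L, length(plots), length(species),
                dimnames = list(plots, species))
  for (p in plots) occ[p, occ_list[[p]]] <- 1L
  category <- category %||% rep("interior", length(plots))
  meta <- tibble::tibble(plot_id = plots,
                         site_id = paste0("s", seq_along(plots)),
                         road_id = "r1", category = category)
  community_matrix(occ, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
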