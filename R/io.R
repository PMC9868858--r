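#' Read a rooted phylogeny or dendrogram from Newick
#'
#' Thin validating wrapper around [ape::read.tree()]. The returned tree is the
#' shared carrier for both the phylogenetic facet (a dated or branch-lengthed
#' phylogeny) and the functional facet (a UPGMA trait dendrogram), so the same
#' branch-set machinery applies to both.
#'
#' Branch lengths absent from the input default to 1 with a warning, so purely
#' topological cladograms remain usable. Internal node labels are tolerated
#' but ignored by all downstream computation.
#'
#' @param x Either a path to a Newick file or a literal Newick string
#'   (detected by the presence of `(` and a terminating `;`).
#' @return An object of class `phylo` with unique tip labels and nonnegative
#'   branch lengths on every edge.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' ape::cophenetic.phylo(tr)["A", "C"] # patristic distance 4
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!nzchar(trimws(x))) abort("empty Newick string")
  is_text <- grepl("[();]", x)
  text <- if (is_text) x else {
    if (!file.exists(x)) abort(paste0("Newick input not found: '", x, "'"))
    paste(readLines(x, warn = FALSE), collapse = "")
  }
  if (!nzchar(trimws(text))) abort("empty Newick string")
  check_balanced_parens(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("Newick parse error: no tree found in input")
  validate_tree(tree)
}

check_balanced_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(paste0("Newick parse error: unbalanced ')' at offset ", i))
      }
    }
  }
  if (depth > 0L) {
    abort(paste0(
      "Newick parse error: ", depth, " unclosed '(' by offset ", length(chars)
    ))
  }
  invisible(TRUE)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) {
    dups <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate tip labels: ", paste(dups, collapse = ", ")))
  }
  if (is.null(tree$edge.length)) {
    warn("tree has no branch lengths; defaulting every edge to 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warn("tree has edges without branch lengths; defaulting those to 1")
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (any(tree$edge.length < 0)) abort("negative branch lengths are not allowed")
  tree
}

#' Serialize a phylogeny to Newick
#'
#' Inverse of [read_newick()]: `read_newick(write_newick(t))` preserves
#' topology, tip labels and branch lengths (15 significant digits).
#'
#' @param tree A `phylo` object.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to `file`).
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree, digits = 15)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Construct a plot-by-species community matrix
#'
#' Bundles a binary plot x species incidence matrix with per-plot metadata
#' (site, road, plot category). Plot categories follow the paired sampling
#' design: each survey site contributes one `roadside` and one `interior`
#' plot.
#'
#' @param occupancy Numeric or logical matrix, plots in rows and species in
#'   columns, with row and column names; entries must be 0/1.
#' @param meta Data frame with columns `plot_id`, `site_id`, `road_id`,
#'   `category`; one row per occupancy row, matched by `plot_id`.
#' @return An object of class `community_matrix`: a list with elements
#'   `occupancy` (integer matrix) and `meta` (tibble).
#' @export
community_matrix <- function(occupancy, meta) {
  occupancy <- as.matrix(occupancy)
  if (is.null(rownames(occupancy)) || is.null(colnames(occupancy))) {
    abort("occupancy must have plot row names and species column names")
  }
  if (anyDuplicated(rownames(occupancy))) abort("duplicated plot id in occupancy")
  if (anyDuplicated(colnames(occupancy))) abort("duplicated species id in occupancy")
  mode(occupancy) <- "numeric"
  if (anyNA(occupancy) || !all(occupancy %in% c(0, 1))) {
    bad <- which(!(occupancy %in% c(0, 1)) | is.na(occupancy))[1]
    abort(paste0(
      "occupancy must be binary; offending cell [",
      rownames(occupancy)[(bad - 1) %% nrow(occupancy) + 1], ", ",
      colnames(occupancy)[(bad - 1) %/% nrow(occupancy) + 1], "]"
    ))
  }
  storage.mode(occupancy) <- "integer"
  empty <- rownames(occupancy)[rowSums(occupancy) == 0]
  if (length(empty)) {
    abort(paste0("empty plot (zero species): ", paste(empty, collapse = ", ")))
  }
  meta <- as_tibble(meta)
  need <- c("plot_id", "site_id", "road_id", "category")
  if (!all(need %in% names(meta))) {
    abort(paste0("meta must have columns ", paste(need, collapse = ", ")))
  }
  meta$category <- tolower(as.character(meta$category))
  bad_cat <- setdiff(unique(meta$category), c("roadside", "interior"))
  if (length(bad_cat)) {
    abort(paste0("unknown plot category: ", paste(bad_cat, collapse = ", "),
                 " (must be 'roadside' or 'interior')"))
  }
  if (anyDuplicated(meta$plot_id)) abort("duplicated plot id in metadata")
  if (!setequal(meta$plot_id, rownames(occupancy))) {
    abort("meta plot ids must match occupancy row names")
  }
  meta <- meta[match(rownames(occupancy), meta$plot_id), ]
  structure(list(occupancy = occupancy, meta = meta), class = "community_matrix")
}

#' @export
print.community_matrix <- function(x, ...) {
  cat("<community_matrix> ", nrow(x$occupancy), " plots x ",
      ncol(x$occupancy), " species\n", sep = "")
  cat("  categories: ",
      paste(sprintf("%s (%d)", names(table(x$meta$category)),
                    table(x$meta$category)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Check the paired roadside/interior design
#'
#' Verifies that every site contributes exactly one roadside and one interior
#' plot, the design required by the paired comparison statistics.
#'
#' @param comm A [community_matrix()].
#' @return `comm`, invisibly, or an error describing the unpaired sites.
#' @export
check_paired_design <- function(comm) {
  stopifnot(inherits(comm, "community_matrix"))
  tab <- table(comm$meta$site_id, comm$meta$category)
  ok <- all(dim(tab) == c(nrow(tab), 2L)) && all(tab == 1L)
  if (!ok) {
    bad <- rownames(tab)[apply(tab != 1L, 1, any)]
    abort(paste0("unpaired design at site(s): ", paste(bad, collapse = ", ")))
  }
  invisible(comm)
}

#' Read a community matrix from CSV
#'
#' Expects one row per plot with metadata columns `plot_id`, `site_id`,
#' `road_id`, `category` followed by one 0/1 column per species. Category
#' strings are case-insensitive and must map onto roadside/interior.
#'
#' @param file Path to a CSV file.
#' @return A [community_matrix()].
#' @export
read_community_matrix <- function(file) {
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  need <- c("plot_id", "site_id", "road_id", "category")
  if (!all(need %in% names(df))) {
    abort(paste0("community CSV must have columns ", paste(need, collapse = ", ")))
  }
  sp_cols <- setdiff(names(df), need)
  if (!length(sp_cols)) abort("community CSV has no species columns")
  occ <- as.matrix(df[sp_cols])
  rownames(occ) <- df$plot_id
  community_matrix(occ, df[need])
}

#' Write a community matrix to CSV
#'
#' @param comm A [community_matrix()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_community_matrix <- function(comm, file) {
  stopifnot(inherits(comm, "community_matrix"))
  df <- dplyr::bind_cols(comm$meta, as_tibble(comm$occupancy))
  readr::write_csv(df, file, progress = FALSE)
  invisible(file)
}

#' Construct a species-by-trait table with declared column types
#'
#' Mixed quantitative/categorical trait tables feed the Gower distance;
#' every column's type must be declared explicitly (there is no automatic
#' ordinal detection). Missing values stay missing - nothing is imputed.
#'
#' @param data Data frame with a `species_id` column plus one column per
#'   trait.
#' @param types Named character vector mapping every trait column to
#'   `"quantitative"` or `"categorical"`.
#' @return An object of class `trait_table`: list with `data` (tibble) and
#'   `types`.
#' @export
trait_table <- function(data, types) {
  data <- as_tibble(data)
  if (!"species_id" %in% names(data)) abort("trait data must have a species_id column")
  if (anyDuplicated(data$species_id)) {
    abort(paste0("duplicated species row: ",
                 paste(unique(data$species_id[duplicated(data$species_id)]),
                       collapse = ", ")))
  }
  trait_cols <- setdiff(names(data), "species_id")
  if (!length(trait_cols)) abort("trait table has no trait columns")
  undeclared <- setdiff(trait_cols, names(types))
  if (length(undeclared)) {
    abort(paste0("undeclared column type for: ", paste(undeclared, collapse = ", ")))
  }
  types <- types[trait_cols]
  bad <- types[!types %in% c("quantitative", "categorical")]
  if (length(bad)) {
    abort(paste0("trait types must be 'quantitative' or 'categorical', got: ",
                 paste(unique(bad), collapse = ", ")))
  }
  for (tc in trait_cols) {
    if (types[[tc]] == "quantitative") {
      v <- data[[tc]]
      if (is.character(v)) {
        num <- suppressWarnings(as.numeric(v))
        if (any(!is.na(v) & nzchar(trimws(v)) & is.na(num))) {
          abort(paste0("non-numeric value in quantitative trait '", tc, "'"))
        }
        v <- num
      }
      if (!is.numeric(v)) abort(paste0("quantitative trait '", tc, "' is not numeric"))
      if (any(is.infinite(v))) abort(paste0("non-finite value in trait '", tc, "'"))
      data[[tc]] <- as.numeric(v)
    } else {
      data[[tc]] <- as.character(data[[tc]])
      data[[tc]][!is.na(data[[tc]]) & !nzchar(trimws(data[[tc]]))] <- NA_character_
    }
  }
  structure(list(data = data, types = types), class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("<trait_table> ", nrow(x$data), " species x ", length(x$types),
      " traits (", sum(x$types == "quantitative"), " quantitative, ",
      sum(x$types == "categorical"), " categorical)\n", sep = "")
  n_miss <- sum(is.na(x$data[names(x$types)]))
  if (n_miss) cat("  missing values: ", n_miss, "\n", sep = "")
  invisible(x)
}

#' Read a trait table from CSV
#'
#' @param file Path to a CSV keyed by `species_id`.
#' @param types Named character vector declaring each trait column
#'   `"quantitative"` or `"categorical"`.
#' @return A [trait_table()].
#' @export
read_trait_table <- function(file, types) {
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  trait_table(df, types)
}

#' Write a trait table (and its type declaration) to CSV
#'
#' @param traits A [trait_table()].
#' @param file Output path for the values; the type declaration goes to a
#'   sibling file `<file stem>_types.csv` with columns `trait`, `type`.
#' @return A character vector of the two paths, invisibly.
#' @export
write_trait_table <- function(traits, file) {
  stopifnot(inherits(traits, "trait_table"))
  readr::write_csv(traits$data, file, progress = FALSE)
  type_file <- paste0(sub("\\.csv$", "", file), "_types.csv")
  readr::write_csv(
    tibble(trait = names(traits$types), type = unname(traits$types)),
    type_file, progress = FALSE
  )
  invisible(c(file, type_file))
}

#' Read a plot-by-soil-variable table from CSV
#'
#' One row per plot (`plot_id` column) and one quantitative column per soil
#' variable (pH, EC, SOM, TN, TP, AP, NH4N, NO3N, CEC, BK in the reference
#' design); all values must be finite.
#'
#' @param file Path to a CSV file.
#' @return A tibble with `plot_id` and numeric soil columns.
#' @export
read_soil_table <- function(file) {
  df <- readr::read_csv(file, show_col_types = FALSE, progress = FALSE)
  validate_soil_table(df)
}

validate_soil_table <- function(df) {
  df <- as_tibble(df)
  if (!"plot_id" %in% names(df)) abort("soil table must have a plot_id column")
  if (anyDuplicated(df$plot_id)) abort("duplicated plot id in soil table")
  vars <- setdiff(names(df), "plot_id")
  if (!length(vars)) abort("soil table has no variable columns")
  for (v in vars) {
    if (!is.numeric(df[[v]])) abort(paste0("soil variable '", v, "' is not numeric"))
    if (any(!is.finite(df[[v]]))) abort(paste0("non-finite value in soil variable '", v, "'"))
  }
  df
}

#' Write a soil table to CSV
#'
#' @param soil Tibble as returned by [read_soil_table()] or [simulate_soil()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_soil_table <- function(soil, file) {
  readr::write_csv(validate_soil_table(soil), file, progress = FALSE)
  invisible(file)
}
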