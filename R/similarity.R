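# Classification of classes by epigenomic profile: Pearson correlation of
# signed-score profiles with best-partner reporting, and hierarchical
# clustering with Chebyshev (maximum) distance and Ward agglomeration.

#' Pearson correlation of class enrichment profiles
#'
#' Correlates the signed-score profiles of every pair of classes over a
#' subset of tracks. The default subset applies the presence rule only
#' (tracks with `p_adj < alpha` in at least one class); the SD filter is
#' not applied here. Classes with a constant profile have undefined
#' correlations: their entries are `NA` and the class is flagged, never
#' zero-filled.
#'
#' @param matrix An `enrichment_matrix`.
#' @param tracks `"significant"` (presence rule at `alpha`, default) or
#'   `"all"`.
#' @param alpha Significance cutoff for the presence rule.
#' @return A `correlation_matrix`: list with `labels`, `r` (n x n, symmetric,
#'   unit diagonal for non-constant profiles), `undefined` (flagged class
#'   labels), `n_tracks` used.
#' @export
pearson_profiles <- function(matrix, tracks = c("significant", "all"),
                             alpha = 0.01) {
  stopifnot(inherits(matrix, "enrichment_matrix"))
  tracks <- match.arg(tracks)
  keep <- if (tracks == "all") {
    rep(TRUE, length(matrix$track_labels))
  } else {
    apply(matrix$p_adj, 2L, min) < alpha
  }
  if (sum(keep) < 3L) {
    stop("correlation analysis needs at least 3 tracks in the selected subset (got ",
         sum(keep), ")")
  }
  x <- matrix$scores[, keep, drop = FALSE]
  constant <- apply(x, 1L, stats::sd) == 0
  r <- suppressWarnings(stats::cor(t(x)))
  r[constant, ] <- NA_real_
  r[, constant] <- NA_real_
  dimnames(r) <- list(matrix$class_labels, matrix$class_labels)
  structure(
    list(labels = matrix$class_labels, r = r,
         undefined = matrix$class_labels[constant],
         n_tracks = sum(keep)),
    class = "correlation_matrix"
  )
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d classes over %d tracks",
              length(x$labels), x$n_tracks))
  if (length(x$undefined)) {
    cat("; undefined profiles: ", paste(x$undefined, collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Best correlated and anticorrelated partner per class
#'
#' For each class, the other class with the highest and the lowest Pearson
#' correlation of enrichment profiles. Ties break to the earlier label in
#' the matrix's label order; undefined (NA) entries are excluded.
#'
#' @param corr A `correlation_matrix` from [pearson_profiles()].
#' @return Data.frame: `class`, `best_partner`, `best_r`, `worst_partner`,
#'   `worst_r`. Rows for classes whose correlations are all undefined carry
#'   `NA`.
#' @export
best_partners <- function(corr) {
  stopifnot(inherits(corr, "correlation_matrix"))
  n <- length(corr$labels)
  if (n < 2L) stop("partner analysis needs at least 2 classes")
  rows <- lapply(seq_len(n), function(i) {
    v <- corr$r[i, ]
    v[i] <- NA_real_
    if (all(is.na(v))) {
      data.frame(class = corr$labels[i],
                 best_partner = NA_character_, best_r = NA_real_,
                 worst_partner = NA_character_, worst_r = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(class = corr$labels[i],
                 best_partner = corr$labels[which.max(v)],
                 best_r = max(v, na.rm = TRUE),
                 worst_partner = corr$labels[which.min(v)],
                 worst_r = min(v, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Chebyshev (maximum) distances between profile vectors
#'
#' `d(u, v) = max_i |u_i - v_i|` between rows (or columns) of a matrix.
#'
#' @param x A numeric matrix or an `enrichment_matrix` (its scores).
#' @param axis `"rows"` (default) or `"columns"`.
#' @return A `dist` object.
#' @export
chebyshev_distances <- function(x, axis = c("rows", "columns")) {
  axis <- match.arg(axis)
  if (inherits(x, "enrichment_matrix")) x <- x$scores
  if (axis == "columns") x <- t(x)
  if (nrow(x) < 2L) stop("need at least 2 vectors")
  stats::dist(x, method = "maximum")
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering by the Ward criterion via Lance-Williams
#' updates applied to the supplied distances as given (`hclust` method
#' `"ward.D"`, the behaviour of classical implementations that do not
#' pre-square); `squared = TRUE` switches to the squared-distance variant
#' (`"ward.D2"`).
#'
#' @param dist A `dist` object or a symmetric numeric matrix with zero
#'   diagonal.
#' @param squared Use the squared-distance Ward variant (default `FALSE`).
#' @return An `hclust` object (n - 1 merges, heights non-decreasing).
#' @export
ward_linkage <- function(dist, squared = FALSE) {
  if (is.matrix(dist)) {
    if (!isSymmetric(unname(dist), tol = 1e-8)) {
      stop("distance matrix must be symmetric")
    }
    if (any(abs(diag(dist)) > 1e-8)) {
      stop("distance matrix must have a zero diagonal")
    }
    dist <- stats::as.dist(dist)
  }
  if (!inherits(dist, "dist")) stop("expected a dist object or matrix")
  if (attr(dist, "Size") < 2L) stop("need at least 2 leaves")
  stats::hclust(dist, method = if (squared) "ward.D2" else "ward.D")
}

#' Export a dendrogram as a Newick string
#'
#' Merge heights become branch lengths.
#'
#' @param hc An `hclust` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
export_newick <- function(hc, path) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Export a clustered heatmap and the reordered matrix
#'
#' Draws the signed-score matrix with a diverging blue-black-yellow palette
#' on a colour scale symmetric about 0 (blue = depleted, yellow = enriched),
#' rows/columns ordered by the supplied dendrograms, and writes the
#' reordered numeric table alongside. `cap` clips the displayed (and
#' exported-table) values to `[-cap, cap]` for legibility; the analysis
#' matrix itself is never modified.
#'
#' @param matrix An `enrichment_matrix` or a numeric matrix with dimnames.
#' @param row_dendro,col_dendro Optional `hclust` objects whose labels match
#'   the matrix dimnames; `NULL` keeps the given order.
#' @param path Output image path (`.png` or `.pdf`, via pheatmap).
#' @param table_path Optional path for the reordered TSV table.
#' @param cap Optional display cap (absolute score).
#' @return Invisibly, a list with the reordered (display) matrix and paths.
#' @export
heatmap_export <- function(matrix, row_dendro = NULL, col_dendro = NULL,
                           path, table_path = NULL, cap = NULL) {
  x <- if (inherits(matrix, "enrichment_matrix")) matrix$scores else matrix
  if (!is.null(row_dendro)) {
    stopifnot(inherits(row_dendro, "hclust"),
              setequal(row_dendro$labels, rownames(x)))
    x <- x[row_dendro$labels[row_dendro$order], , drop = FALSE]
  }
  if (!is.null(col_dendro)) {
    stopifnot(inherits(col_dendro, "hclust"),
              setequal(col_dendro$labels, colnames(x)))
    x <- x[, col_dendro$labels[col_dendro$order], drop = FALSE]
  }
  if (!is.null(cap)) x <- pmin(pmax(x, -cap), cap)
  lim <- max(abs(x), na.rm = TRUE)
  if (!is.finite(lim) || lim <= 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#1F4EFF", "#000000", "#FFE000"))(100)
  pheatmap::pheatmap(
    x, cluster_rows = FALSE, cluster_cols = FALSE,
    color = pal, breaks = seq(-lim, lim, length.out = 101),
    border_color = NA, silent = TRUE, filename = path
  )
  if (!is.null(table_path)) write_matrix_tsv(x, table_path)
  invisible(list(matrix = x, image = path, table = table_path))
}
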