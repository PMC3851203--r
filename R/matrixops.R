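# Assembly and filtering of the classes x tracks signed-score matrix, and
# per-class variability summaries.

#' Assemble the classes x tracks enrichment matrix
#'
#' Builds parallel matrices of signed scores, adjusted p-values and
#' directions from a complete set of per-pair results. Rows and columns
#' follow first-seen order in `results`; every (class, track) pair must
#' appear exactly once.
#'
#' @param results Data.frame with columns `class`, `track`, `score`,
#'   `p_adj`, `direction` (as from [enrich_classes()]).
#' @return An `enrichment_matrix`: list with `class_labels`, `track_labels`,
#'   and matrices `scores`, `p_adj`, `directions`.
#' @export
assemble_matrix <- function(results) {
  needed <- c("class", "track", "score", "p_adj", "direction")
  if (!all(needed %in% names(results))) {
    stop("results must have columns: ", paste(needed, collapse = ", "))
  }
  classes <- unique(results$class)
  tracks <- unique(results$track)
  key <- paste(results$class, results$track, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    pair <- strsplit(dup[1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("duplicate result for pair (%s, %s)", pair[1L], pair[2L]))
  }
  all_keys <- as.vector(outer(classes, tracks, paste, sep = "\r"))
  miss <- setdiff(all_keys, key)
  if (length(miss)) {
    pair <- strsplit(miss[1L], "\r", fixed = TRUE)[[1L]]
    stop(sprintf("missing result for pair (%s, %s)", pair[1L], pair[2L]))
  }

  shape <- function(v, fill) {
    m <- matrix(fill, nrow = length(classes), ncol = length(tracks),
                dimnames = list(classes, tracks))
    m[cbind(match(results$class, classes), match(results$track, tracks))] <- v
    m
  }
  structure(
    list(
      class_labels = classes,
      track_labels = tracks,
      scores = shape(results$score, NA_real_),
      p_adj = shape(results$p_adj, NA_real_),
      directions = shape(results$direction, NA_character_)
    ),
    class = "enrichment_matrix"
  )
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat(sprintf("<enrichment_matrix> %d classes x %d tracks\n",
              length(x$class_labels), length(x$track_labels)))
  invisible(x)
}

subset_matrix_tracks <- function(em, keep) {
  structure(
    list(
      class_labels = em$class_labels,
      track_labels = em$track_labels[keep],
      scores = em$scores[, keep, drop = FALSE],
      p_adj = em$p_adj[, keep, drop = FALSE],
      directions = em$directions[, keep, drop = FALSE]
    ),
    class = "enrichment_matrix"
  )
}

#' Apply the presence and SD track filters
#'
#' A track is kept iff (i) at least one class reaches `p_adj < alpha`
#' (presence rule), and (ii) the sample standard deviation (n-1 denominator)
#' of its signed scores across classes is at least `sd_min`, i.e. the track
#' discriminates among classes. `alpha = 1` disables the presence rule and
#' `sd_min = 0` disables the SD rule, making the filter the identity. Class
#' rows are never removed; surviving columns keep their order, so the filter
#' is idempotent.
#'
#' @param matrix An `enrichment_matrix`.
#' @param alpha Significance cutoff in `(0, 1]` (default 0.01).
#' @param sd_min Minimum across-class score SD (default 2.0).
#' @return A filtered `enrichment_matrix` (possibly with 0 tracks).
#' @export
filter_tracks <- function(matrix, alpha = 0.01, sd_min = 2.0) {
  stopifnot(inherits(matrix, "enrichment_matrix"),
            alpha > 0, alpha <= 1, sd_min >= 0)
  min_p <- apply(matrix$p_adj, 2L, min)
  sds <- apply(matrix$scores, 2L, stats::sd)
  present <- if (alpha >= 1) rep(TRUE, length(min_p)) else min_p < alpha
  varied <- if (sd_min <= 0) rep(TRUE, length(sds)) else !is.na(sds) & sds >= sd_min
  subset_matrix_tracks(matrix, present & varied)
}

#' Per-class score variability and its relation to class size
#'
#' Computes the sample SD of each class's signed scores across all tracks
#' of the (unfiltered) matrix, and the Pearson correlation between class
#' size and score SD, with and without a configurable excluded label set
#' (classes whose extreme profiles dominate the relationship can be set
#' aside).
#'
#' @param matrix An `enrichment_matrix` with at least 2 tracks.
#' @param sizes Named numeric vector of member counts covering all classes.
#' @param exclude Class labels excluded from the second correlation.
#' @return A `class_variability` list: `table` (class, size, score_sd),
#'   `size_sd_cor`, `size_sd_cor_excluded` (each `NA` when fewer than 3
#'   classes contribute), `exclude`.
#' @export
class_variability <- function(matrix, sizes, exclude = character()) {
  stopifnot(inherits(matrix, "enrichment_matrix"))
  if (length(matrix$track_labels) < 2L) {
    stop("class variability needs at least 2 tracks")
  }
  missing <- setdiff(matrix$class_labels, names(sizes))
  if (length(missing)) {
    stop("sizes missing for class(es): ", paste(missing, collapse = ", "))
  }
  tab <- data.frame(
    class = matrix$class_labels,
    size = as.numeric(sizes[matrix$class_labels]),
    score_sd = apply(matrix$scores, 1L, stats::sd),
    stringsAsFactors = FALSE
  )
  safe_cor <- function(d) {
    if (nrow(d) < 3L || stats::sd(d$size) == 0 || stats::sd(d$score_sd) == 0) {
      NA_real_
    } else {
      stats::cor(d$size, d$score_sd)
    }
  }
  structure(
    list(
      table = tab,
      size_sd_cor = safe_cor(tab),
      size_sd_cor_excluded = safe_cor(tab[!tab$class %in% exclude, , drop = FALSE]),
      exclude = exclude
    ),
    class = "class_variability"
  )
}

#' Write a labelled numeric matrix as TSV
#'
#' Class rows x track columns, first column carrying the row labels.
#'
#' @param m A matrix with dimnames, or an `enrichment_matrix` (its scores).
#' @param path Output path.
#' @param row_label Header for the row-label column.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path, row_label = "class") {
  if (inherits(m, "enrichment_matrix")) m <- m$scores
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- row_label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
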