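# Core enrichment statistic: member-centric overlap counting, a pooled
# background sampled without replacement, a chi-square enrichment/depletion
# test, BH correction, and the signed -log10 score.
#
# The null model: pseudo-classes of the same size as the class under test are
# drawn from the pooled universe of all query classes (the tested class is
# NOT excluded), so enrichment is measured relative to the family universe,
# not the whole genome. Because each pool member's overlap status with a
# fixed track is itself fixed, the null count is exactly hypergeometric; the
# sampled mean/variance converge to k*M/N and k*(M/N)(1-M/N)(N-k)/(N-1).

#' Count query members overlapping an annotation track
#'
#' Member-centric counting: a query member overlapping several annotation
#' intervals of the same track contributes exactly 1.
#'
#' @param query A `GRanges` of class members.
#' @param index An `interval_index` or annotation `GRanges`.
#' @param class_label,track_label Optional labels stored on the result.
#' @return An `overlap_count` list: `class_label`, `track_label`, `observed`,
#'   `class_size`. An empty query gives `observed = 0`.
#' @export
count_overlapping_members <- function(query, index,
                                      class_label = NULL, track_label = NULL) {
  observed <- sum(overlaps_any(query, index))
  structure(
    list(
      class_label = class_label %||%
        (S4Vectors::metadata(query)$label %||% "query"),
      track_label = track_label %||%
        (if (inherits(index, "interval_index")) index$label else "annotation"),
      observed = as.integer(observed),
      class_size = length(query)
    ),
    class = "overlap_count"
  )
}

#' Draw a random pseudo-class from the pooled universe
#'
#' Samples `k` distinct members uniformly without replacement. Uses the
#' current RNG state unless `seed` is given.
#'
#' @param pool A `GRanges`: the union of all query classes.
#' @param k Number of members to draw (`1 <= k <= length(pool)`).
#' @param seed Optional integer seed for a reproducible draw.
#' @return A `GRanges` of `k` pool members.
#' @export
sample_background <- function(pool, k, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > length(pool)) {
    stop("k must satisfy 1 <= k <= pool size (", length(pool), "); got ", k)
  }
  if (!is.null(seed)) set.seed(seed)
  pool[sample.int(length(pool), k)]
}

# Null overlap counts for a class of size k against a fixed overlap-status
# vector; the workhorse shared by estimate_null() and enrich_classes().
null_counts <- function(status, k, n_samplings) {
  n_pool <- length(status)
  vapply(seq_len(n_samplings),
         function(i) sum(status[sample.int(n_pool, k)]),
         numeric(1))
}

#' Estimate the sampled null distribution of overlap counts
#'
#' Repeatedly draws pseudo-classes of size `k` from the pool and records how
#' many members overlap the track, yielding the empirical mean and variance
#' of the null overlap count.
#'
#' @inheritParams sample_background
#' @param index An `interval_index` or annotation `GRanges` (the track).
#' @param n_samplings Number of random pseudo-classes (default 1000).
#' @param keep_samples If `TRUE`, retain the per-sampling counts.
#' @return A `null_distribution` list: `mean`, `variance` (sample variance,
#'   0 when `n_samplings == 1`), `n_samplings`, and optionally
#'   `sample_counts`.
#' @export
estimate_null <- function(pool, index, k, n_samplings = 1000, seed = NULL,
                          keep_samples = FALSE) {
  if (n_samplings < 1) stop("n_samplings must be >= 1")
  if (k < 1 || k > length(pool)) {
    stop("k must satisfy 1 <= k <= pool size (", length(pool), "); got ", k)
  }
  if (!is.null(seed)) set.seed(seed)
  status <- overlaps_any(pool, index)
  counts <- null_counts(status, k, n_samplings)
  structure(
    list(
      mean = mean(counts),
      variance = if (n_samplings > 1) stats::var(counts) else 0,
      n_samplings = as.integer(n_samplings),
      sample_counts = if (keep_samples) counts else NULL
    ),
    class = "null_distribution"
  )
}

#' Chi-square test of observed vs expected overlap counts
#'
#' Default construction: Pearson chi-square on the 2x2 table
#' `[[observed, class_size - observed], [expected, class_size - expected]]`
#' with df = 1 and no continuity correction, where `expected` is the sampled
#' null mean. `kind = "gof"` gives the one-sample goodness-of-fit variant
#' `(O - E)^2 * (1/E + 1/(size - E))`, which treats the expected count as
#' known; it is better calibrated against the sampling null (see the package
#' vignette) but is not the default construction.
#'
#' @param observed Observed overlap count (`0 <= observed <= class_size`).
#' @param class_size Number of members in the class.
#' @param null A `null_distribution`, or a single numeric expected count.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @param kind `"independence"` (2x2 table, default) or `"gof"`.
#' @return A list: `chi2`, `p_raw`, `direction` (one of `"enriched"`,
#'   `"depleted"`, `"none"`). Degenerate tables (expected at 0 or
#'   `class_size` with observed equal to it, or observed == expected) give
#'   `chi2 = 0`, `p = 1`, `direction = "none"`.
#' @export
chi_square_test <- function(observed, class_size, null, correct = FALSE,
                            kind = c("independence", "gof")) {
  kind <- match.arg(kind)
  expected <- if (is.list(null)) null$mean else null
  if (observed < 0 || observed > class_size) {
    stop("observed must lie in [0, class_size]")
  }
  if (expected < 0 || expected > class_size) {
    stop("expected must lie in [0, class_size]")
  }
  direction <- if (observed > expected) "enriched"
    else if (observed < expected) "depleted" else "none"
  degenerate <- observed == expected ||
    (expected <= 0 && observed <= 0) ||
    (expected >= class_size && observed >= class_size)
  if (degenerate) {
    return(list(chi2 = 0, p_raw = 1, direction = "none"))
  }
  if (kind == "independence") {
    a <- observed; b <- class_size - observed
    cc <- expected; d <- class_size - expected
    n <- 2 * class_size
    num <- abs(a * d - b * cc)
    if (correct) num <- max(0, num - n / 2)
    denom <- class_size * class_size * (a + cc) * (b + d)
    chi2 <- if (denom <= 0) 0 else n * num^2 / denom
  } else {
    if (expected <= 0 || expected >= class_size) {
      # one-sample form needs expected strictly inside (0, class_size)
      chi2 <- Inf
    } else {
      delta <- abs(observed - expected)
      if (correct) delta <- max(0, delta - 0.5)
      chi2 <- delta^2 * (1 / expected + 1 / (class_size - expected))
    }
  }
  list(chi2 = chi2,
       p_raw = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       direction = direction)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment, order-preserving with the input and clipped to 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as the input.
#' @export
adjust_bh <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must be numeric and lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Signed -log10 transform of adjusted p-values
#'
#' `-log10(p_adj)` with a negative sign for depleted associations and 0 for
#' `direction = "none"`. `p_adj` is floored at `min_p` before the log so
#' underflowed p-values map to a finite score.
#'
#' @param p_adj Adjusted p-values in `[0, 1]`.
#' @param direction Character vector: `"enriched"`, `"depleted"` or `"none"`.
#' @param min_p Floor applied to `p_adj` (default `1e-300`).
#' @return Numeric scores in decimal log units.
#' @export
signed_score <- function(p_adj, direction, min_p = 1e-300) {
  if (any(p_adj < 0 | p_adj > 1, na.rm = TRUE)) {
    stop("p_adj must lie in [0, 1]")
  }
  s <- -log10(pmax(p_adj, min_p))
  ifelse(direction == "enriched", s,
         ifelse(direction == "depleted", -s, 0))
}

# Deterministic per-(class, track) RNG substream seed, derived from the
# master seed and the alphabetical ranks of the labels so results do not
# depend on evaluation order.
pair_seed <- function(seed, class_rank, track_rank) {
  s0 <- as.double(seed) %% 2147483647
  as.integer((s0 * 7919 + class_rank * 104729 + track_rank) %% 2147483647)
}

#' Enrichment analysis of every class against every track
#'
#' For each (class, track) pair: counts class members overlapping the track
#' (member-centric), estimates the null overlap count by `n_samplings`
#' random pseudo-classes of the same size drawn from the pooled universe of
#' all classes, applies the chi-square test, adjusts p-values by
#' Benjamini-Hochberg (per class across tracks, or globally), and computes
#' the signed -log10 score. RNG substreams are derived per pair from the
#' master seed, so results are identical regardless of evaluation order.
#'
#' @param classes Named list of query `GRanges` (one per class).
#' @param tracks Named list of annotation `GRanges` (one per track).
#' @param n_samplings Random samplings per pair (default 1000).
#' @param seed Master integer seed.
#' @param bh_scope `"per_class"` (adjust across tracks within each class,
#'   default) or `"global"` (across all pairs).
#' @param min_p Floor for adjusted p-values before the log transform.
#' @param chisq_kind,correct Passed to [chi_square_test()].
#' @return A data.frame with one row per (class, track) pair, in class-major
#'   input order: `class`, `track`, `observed`, `expected`, `variance`,
#'   `chi2`, `p_raw`, `p_adj`, `direction`, `score`, `class_size`.
#' @export
enrich_classes <- function(classes, tracks, n_samplings = 1000, seed = 1L,
                           bh_scope = c("per_class", "global"),
                           min_p = 1e-300,
                           chisq_kind = c("independence", "gof"),
                           correct = FALSE) {
  bh_scope <- match.arg(bh_scope)
  chisq_kind <- match.arg(chisq_kind)
  if (is.null(names(classes)) || anyDuplicated(names(classes))) {
    stop("classes must be a uniquely named list")
  }
  if (is.null(names(tracks)) || anyDuplicated(names(tracks))) {
    stop("tracks must be a uniquely named list")
  }
  if (n_samplings < 1) stop("n_samplings must be >= 1")

  class_names <- names(classes)
  track_names <- names(tracks)
  sizes <- vapply(classes, length, integer(1))
  if (any(sizes == 0L)) stop("empty class: ", class_names[sizes == 0L][1L])

  # Pool members in sorted-class-label order so that the index -> member
  # mapping (and hence every sampled null) is invariant to input order.
  canon <- order(class_names)
  pool <- suppressWarnings(
    do.call(c, lapply(unname(classes[canon]), function(g) {
      S4Vectors::metadata(g) <- list(); unname(g)
    })))
  n_pool <- length(pool)
  member_class <- rep(canon, sizes[canon])

  # Boolean incidence: pool member x track overlap status, computed once.
  status <- vapply(tracks, function(tr) overlaps_any(pool, tr),
                   logical(n_pool))
  status <- matrix(status, nrow = n_pool,
                   dimnames = list(NULL, track_names))

  class_rank <- match(class_names, sort(class_names))
  track_rank <- match(track_names, sort(track_names))

  n_pairs <- length(classes) * length(tracks)
  out <- data.frame(
    class = rep(class_names, each = length(tracks)),
    track = rep(track_names, times = length(classes)),
    observed = integer(n_pairs), expected = numeric(n_pairs),
    variance = numeric(n_pairs), chi2 = numeric(n_pairs),
    p_raw = numeric(n_pairs), p_adj = NA_real_,
    direction = character(n_pairs), score = NA_real_,
    class_size = rep(sizes, each = length(tracks)),
    stringsAsFactors = FALSE
  )

  row <- 0L
  for (i in seq_along(classes)) {
    rows_i <- which(member_class == i)
    k <- sizes[i]
    for (j in seq_along(tracks)) {
      row <- row + 1L
      set.seed(pair_seed(seed, class_rank[i], track_rank[j]))
      counts <- null_counts(status[, j], k, n_samplings)
      observed <- sum(status[rows_i, j])
      expected <- mean(counts)
      test <- chi_square_test(observed, k, expected,
                              correct = correct, kind = chisq_kind)
      out$observed[row] <- as.integer(observed)
      out$expected[row] <- expected
      out$variance[row] <- if (n_samplings > 1) stats::var(counts) else 0
      out$chi2[row] <- test$chi2
      out$p_raw[row] <- test$p_raw
      out$direction[row] <- test$direction
    }
  }

  out$p_adj <- if (bh_scope == "global") {
    adjust_bh(out$p_raw)
  } else {
    stats::ave(out$p_raw, out$class, FUN = adjust_bh)
  }
  out$score <- signed_score(out$p_adj, out$direction, min_p = min_p)
  out
}

#' Write an enrichment result table
#'
#' Tab-separated with a header line; columns as returned by
#' [enrich_classes()].
#'
#' @param results Data.frame from [enrich_classes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment_table <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
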