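# Independent oracles used to cross-check the package implementation.
# Each one works from first principles (brute force / closed form) and never
# calls the code path it checks.

# O(n*m) all-pairs overlap scan; >= 1 shared nt on the same chromosome
# (1-based closed coordinates, strand ignored).
brute_overlap_any <- function(query, annotation) {
  qc <- as.character(GenomicRanges::seqnames(query))
  qs <- GenomicRanges::start(query); qe <- GenomicRanges::end(query)
  ac <- as.character(GenomicRanges::seqnames(annotation))
  as_ <- GenomicRanges::start(annotation)
  ae <- GenomicRanges::end(annotation)
  vapply(seq_along(query), function(i) {
    any(qc[i] == ac & pmax(qs[i], as_) <= pmin(qe[i], ae))
  }, logical(1))
}

# BH step-up from the definition: p_(i) * m / i with a cumulative minimum
# from the largest rank down, clipped to 1, returned in input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

brute_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

brute_chebyshev <- function(u, v) max(abs(u - v))

# Exhaustive Ward agglomeration: at every step the merge cost of every
# cluster pair is recomputed from the ORIGINAL distance matrix via the
# closed-form Ward cluster distance, and the global minimum is merged.
ward_oracle <- function(dm) {
  n <- nrow(dm)
  cl_dist <- function(A, B) {
    nA <- length(A); nB <- length(B)
    2 * nA * nB / (nA + nB) *
      (sum(dm[A, B, drop = FALSE]) / (nA * nB) -
         sum(dm[A, A, drop = FALSE]) / (2 * nA^2) -
         sum(dm[B, B, drop = FALSE]) / (2 * nB^2))
  }
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  merged_sets <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          d <- cl_dist(clusters[[i]], clusters[[j]])
          if (d < best) { best <- d; bi <- i; bj <- j }
        }
      }
    }
    heights[step] <- best
    clusters[[bi]] <- sort(c(clusters[[bi]], clusters[[bj]]))
    merged_sets[[step]] <- clusters[[bi]]
    clusters[[bj]] <- NULL
  }
  list(height = heights, merged_sets = merged_sets)
}

# Leaf sets created by each merge of an hclust object (representation
# independent of hclust's within-row id ordering).
hclust_merged_sets <- function(hc) {
  n <- nrow(hc$merge) + 1L
  sets <- vector("list", n - 1L)
  expand <- function(id) {
    if (id < 0) -id else sets[[id]]
  }
  for (s in seq_len(n - 1L)) {
    sets[[s]] <- sort(c(expand(hc$merge[s, 1L]), expand(hc$merge[s, 2L])))
  }
  sets
}

# Random interval fixtures on a small multi-chromosome genome.
random_granges <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                           max_len = 200) {
  if (n == 0L) return(GenomicRanges::GRanges())
  chr <- sample(chroms, n, replace = TRUE)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(start = start, width = len))
  names(gr) <- paste0("iv", seq_len(n))
  gr
}

# A complete toy result table for matrix-level tests.
toy_results <- function(scores, alpha_sig = NULL) {
  classes <- rownames(scores); tracks <- colnames(scores)
  df <- expand.grid(class = classes, track = tracks,
                    stringsAsFactors = FALSE)
  df$score <- scores[cbind(df$class, df$track)]
  df$direction <- ifelse(df$score > 0, "enriched",
                         ifelse(df$score < 0, "depleted", "none"))
  df$p_adj <- 10^(-abs(df$score))
  df
}
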