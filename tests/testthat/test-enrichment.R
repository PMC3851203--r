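# The core statistic: member-centric counting, pooled sampled null,
# chi-square test, BH adjustment, signed scores.

test_that("a member overlapping several track intervals counts once", {
  # one tRNA-like member hitting 3 binding sites contributes exactly 1
  member <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  sites <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(90, 140, 190),
                                                   c(110, 160, 210)))
  oc <- count_overlapping_members(member, build_index(sites))
  expect_identical(oc$observed, 1L)

  q <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(c(1, 21, 41), c(10, 30, 50)))
  track <- GenomicRanges::GRanges("chr1", IRanges::IRanges(6, 25))
  expect_identical(count_overlapping_members(q, build_index(track))$observed, 2L)
  expect_identical(
    count_overlapping_members(GenomicRanges::GRanges(),
                              build_index(track))$observed, 0L)
})

test_that("background sampling is uniform, without replacement, reproducible", {
  set.seed(5)
  pool <- random_granges(10)
  full <- sample_background(pool, 10, seed = 3)
  expect_setequal(names(full), names(pool))
  expect_identical(names(sample_background(pool, 4, seed = 9)),
                   names(sample_background(pool, 4, seed = 9)))
  expect_error(sample_background(pool, 11), "1 <= k <= pool size")
  expect_error(sample_background(pool, 0), "1 <= k <= pool size")
  # frequency of each member over many k=1 draws within 4 SD of 1/10
  set.seed(21)
  draws <- table(vapply(1:10000, function(i)
    names(sample_background(pool, 1)), ""))
  se <- sqrt(0.1 * 0.9 / 10000)
  expect_true(all(abs(as.numeric(draws) / 10000 - 0.1) < 4 * se))
})

test_that("sampled null matches the hypergeometric closed form", {
  set.seed(31)
  pool <- random_granges(1000, max_pos = 1e5)
  track <- random_granges(300, max_pos = 1e5)
  idx <- build_index(track)
  M <- sum(overlaps_any(pool, idx))
  N <- 1000; k <- 100
  nd <- estimate_null(pool, idx, k = k, n_samplings = 1000, seed = 8,
                      keep_samples = TRUE)
  exp_mean <- k * M / N
  exp_var <- k * (M / N) * (1 - M / N) * (N - k) / (N - 1)
  se <- sqrt(exp_var / 1000)
  expect_lt(abs(nd$mean - exp_mean), 3 * se)
  expect_lt(abs(nd$variance - exp_var) / exp_var, 0.25)
  expect_length(nd$sample_counts, 1000L)
  # track hitting nothing -> degenerate null
  far <- build_index(GenomicRanges::GRanges("chrZ", IRanges::IRanges(1, 10)))
  nd0 <- estimate_null(pool, far, k = 50, n_samplings = 50, seed = 1)
  expect_identical(nd0$mean, 0)
  expect_identical(nd0$variance, 0)
})

test_that("chi-square test reproduces the 2x2 Pearson statistic", {
  # independent oracle: base chisq.test on the same table, df = 1, no Yates
  oracle <- suppressWarnings(
    stats::chisq.test(matrix(c(50, 50, 25, 75), 2, byrow = TRUE),
                      correct = FALSE))
  t1 <- chi_square_test(50, 100, 25)
  expect_equal(t1$chi2, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(t1$p_raw, oracle$p.value, tolerance = 1e-12)
  expect_identical(t1$direction, "enriched")
  expect_equal(t1$chi2, 13.3333, tolerance = 1e-4)
  expect_equal(t1$p_raw, 2.6e-4, tolerance = 0.01)
  # table symmetry: swapping observed/expected flips direction only
  t2 <- chi_square_test(25, 100, 50)
  expect_equal(t2$chi2, t1$chi2, tolerance = 1e-12)
  expect_identical(t2$direction, "depleted")
  # non-integer expected counts are accepted
  t3 <- chi_square_test(40, 100, 31.42)
  o3 <- suppressWarnings(
    stats::chisq.test(matrix(c(40, 60, 31.42, 68.58), 2, byrow = TRUE),
                      correct = FALSE))
  expect_equal(t3$chi2, unname(o3$statistic), tolerance = 1e-9)
})

test_that("degenerate chi-square tables give chi2 = 0, p = 1, none", {
  for (case in list(c(30, 100, 30), c(0, 50, 0), c(50, 50, 50))) {
    t <- chi_square_test(case[1], case[2], case[3])
    expect_identical(t$chi2, 0)
    expect_identical(t$p_raw, 1)
    expect_identical(t$direction, "none")
  }
  expect_error(chi_square_test(101, 100, 50), "observed")
  expect_error(chi_square_test(10, 100, 150), "expected")
})

test_that("Yates and goodness-of-fit variants behave as documented", {
  plain <- chi_square_test(50, 100, 40)
  yates <- chi_square_test(50, 100, 40, correct = TRUE)
  expect_lt(yates$chi2, plain$chi2)
  gof <- chi_square_test(50, 100, 40, kind = "gof")
  expect_equal(gof$chi2, (50 - 40)^2 * (1 / 40 + 1 / 60), tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force definition", {
  expect_equal(adjust_bh(0.03), 0.03)
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(c(1, 1)), c(1, 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjust_bh(c(0.5, -0.1)), "\\[0, 1\\]")
  set.seed(99)
  for (rep in 1:200) {
    p <- stats::runif(sample(1:40, 1))
    adj <- adjust_bh(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))  # monotone: adjusted >= raw
    expect_true(all(adj <= 1))
  }
})

test_that("signed scores are antisymmetric in direction and floored", {
  expect_equal(signed_score(0.01, "enriched"), 2)
  expect_equal(signed_score(0.01, "depleted"), -2)
  expect_equal(signed_score(1, "enriched"), 0)
  expect_equal(signed_score(0.3, "none"), 0)
  expect_equal(signed_score(0, "enriched"), 300)  # default floor 1e-300
  expect_equal(signed_score(0, "depleted", min_p = 1e-20), -20)
  set.seed(4)
  p <- stats::runif(50)
  expect_equal(signed_score(p, rep("enriched", 50)),
               -signed_score(p, rep("depleted", 50)))
  expect_error(signed_score(1.5, "enriched"), "\\[0, 1\\]")
})

test_that("enrich_classes is deterministic and order-independent", {
  set.seed(17)
  genome <- c(chrS1 = 1e6)
  tr <- list(tA = generate_track(genome, 60, 0.2, "tA"),
             tB = generate_track(genome, 60, 0.1, "tB"))
  cls <- list(c1 = generate_class(genome, 80, 30, 120, 400, "c1"),
              c2 = generate_class(genome, 120, 30, 120, 400, "c2"))
  r1 <- enrich_classes(cls, tr, n_samplings = 100, seed = 42)
  r2 <- enrich_classes(cls, tr, n_samplings = 100, seed = 42)
  expect_identical(r1, r2)
  # reversing input order changes row order but not any pair's numbers
  r3 <- enrich_classes(rev(cls), rev(tr), n_samplings = 100, seed = 42)
  key <- function(d) d[order(d$class, d$track), ]
  expect_equal(key(r1), key(r3), ignore_attr = TRUE)
  # a different seed changes the sampled null
  r4 <- enrich_classes(cls, tr, n_samplings = 100, seed = 43)
  expect_false(identical(r1$expected, r4$expected))
})

test_that("enrich_classes output satisfies the result invariants", {
  set.seed(23)
  genome <- c(chrS1 = 1e6)
  tr <- list(tA = generate_track(genome, 80, 0.25, "tA"),
             tB = generate_track(genome, 40, 0.08, "tB"),
             tC = generate_track(genome, 50, 0.15, "tC"))
  cls <- list(up = generate_class(genome, 150, 30, 120, 400, "up",
                                  effect = list(track = tr$tA, multiplier = 2)),
              flat = generate_class(genome, 150, 30, 120, 400, "flat"))
  res <- enrich_classes(cls, tr, n_samplings = 300, seed = 7)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$observed >= 0 & res$observed <= res$class_size))
  expect_true(all(res$p_raw >= 0 & res$p_raw <= 1))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15 & res$p_adj <= 1))
  expect_true(all((res$direction == "enriched") == (res$observed > res$expected)))
  expect_true(all((res$direction == "depleted") == (res$observed < res$expected)))
  expect_true(all(sign(res$score) == c(enriched = 1, depleted = -1,
                                       none = 0)[res$direction] |
                    res$score == 0))
  # planted pair is the strongest enrichment
  planted <- res[res$class == "up" & res$track == "tA", ]
  expect_identical(planted$direction, "enriched")
  expect_identical(max(res$score), planted$score)
})

test_that("BH scope switches between per-class and global correction", {
  set.seed(29)
  genome <- c(chrS1 = 5e5)
  tr <- list(tA = generate_track(genome, 40, 0.2, "tA"),
             tB = generate_track(genome, 40, 0.1, "tB"))
  cls <- list(c1 = generate_class(genome, 100, 30, 100, 300, "c1"),
              c2 = generate_class(genome, 100, 30, 100, 300, "c2"))
  per <- enrich_classes(cls, tr, n_samplings = 100, seed = 2,
                        bh_scope = "per_class")
  glob <- enrich_classes(cls, tr, n_samplings = 100, seed = 2,
                         bh_scope = "global")
  expect_identical(per$p_raw, glob$p_raw)
  for (cl in c("c1", "c2")) {
    i <- per$class == cl
    expect_equal(per$p_adj[i], brute_bh(per$p_raw[i]), tolerance = 1e-12)
  }
  expect_equal(glob$p_adj, brute_bh(glob$p_raw), tolerance = 1e-12)
})
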