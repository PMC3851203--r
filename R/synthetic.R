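# Synthetic region-set studies with planted, known enrichment effects.
#
# The generator emulates the statistical shape of a family-vs-annotation
# study: ~15 query classes of 50-3,000 short members drawn from right-skewed
# length distributions, and annotation tracks of non-overlapping intervals
# covering configurable genome fractions. A sparse effect map plants a known
# overlap-rate multiplier per (class, track) pair; a member designated as
# overlapping starts inside a randomly chosen track interval (guaranteeing
# >= 1 nt overlap) and otherwise is placed entirely within the track's
# complement, so the planted rate is exact by construction.

#' Catalogue of non-coding RNA classes used for the default study shape
#'
#' Member counts and length ranges (nt) typical of the major human ncRNA
#' families (tRNA, piRNA, snoRNA subfamilies, miRNA, ...), totalling 16,701
#' members across 15 classes. Used by [ncrna_study_spec()] to size the
#' default synthetic study.
#'
#' @return Data.frame: `label`, `size`, `min_len`, `mean_len`, `max_len`.
#' @export
ncrna_class_catalog <- function() {
  data.frame(
    label = c("7SK", "CD_box", "HACA_box", "lncRNA", "miRNA", "piRNA",
              "pri_miRNA", "rRNA", "scaRNA", "snoRNA", "snRNA",
              "spliceosomal", "SRP_RNA", "tRNA", "Y_RNA"),
    size = c(316L, 509L, 440L, 217L, 2233L, 2152L, 1595L, 611L, 52L,
             1001L, 3024L, 1812L, 941L, 905L, 893L),
    min_len = c(61, 30, 52, 36, 15, 20, 41, 34, 82, 30, 30, 49, 201, 59, 57),
    mean_len = c(293, 99, 130, 144, 22, 47, 83, 119, 153, 115, 109, 111,
                 286, 72, 102),
    max_len = c(374, 238, 329, 463, 27, 8302, 180, 1860, 419, 419, 419,
                229, 361, 107, 148),
    stringsAsFactors = FALSE
  )
}

# Right-skewed member lengths: log-normal parameterised so the expectation
# matches mean_len, with spread driven by the max/mean ratio, clamped to the
# stated range.
rlnorm_lengths <- function(n, min_len, mean_len, max_len) {
  sdlog <- log(max(max_len / max(mean_len, 1), 1.05)) / 3
  sdlog <- min(max(sdlog, 0.05), 1.2)
  meanlog <- log(mean_len) - sdlog^2 / 2
  x <- round(stats::rlnorm(n, meanlog, sdlog))
  pmin(pmax(x, min_len), max_len)
}

genome_granges <- function(genome) {
  GenomicRanges::GRanges(names(genome),
                         IRanges::IRanges(start = 1, end = unname(genome)))
}

#' Generate an annotation track of non-overlapping intervals
#'
#' Draws `n_intervals` log-normal interval lengths targeting total coverage
#' `coverage * sum(genome)` (lengths are rescaled if the draw misses the
#' target by more than 8%, so realized coverage is within 10% relative of
#' target), assigns intervals to chromosomes proportionally to length, and
#' places them without self-overlap by distributing the free space uniformly
#' among the gaps.
#'
#' @param genome Named numeric vector of chromosome lengths (nt).
#' @param n_intervals Number of intervals (`0` gives an empty track).
#' @param coverage Target genome fraction covered, in `(0, 0.9]`.
#' @param label Track label.
#' @param cv Coefficient of variation of interval lengths (default 0.3).
#' @return A `GRanges` with `metadata()` label/role, sorted by position.
#' @export
generate_track <- function(genome, n_intervals, coverage, label = "track",
                           cv = 0.3) {
  stopifnot(is.numeric(genome), !is.null(names(genome)), all(genome > 0))
  if (n_intervals == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr) <- list(label = label, role = "annotation")
    return(gr)
  }
  total_genome <- sum(genome)
  if (coverage <= 0 || coverage > 0.9) {
    stop("infeasible coverage ", coverage, ": must lie in (0, 0.9]")
  }
  target <- coverage * total_genome
  mean_len <- target / n_intervals
  sdlog <- sqrt(log(1 + cv^2))
  len <- pmax(1, round(stats::rlnorm(n_intervals,
                                     log(mean_len) - sdlog^2 / 2, sdlog)))
  if (abs(sum(len) - target) / target > 0.08) {
    len <- pmax(1, round(len * target / sum(len)))
  }
  chrom <- sample(names(genome), n_intervals, replace = TRUE,
                  prob = genome / total_genome)
  pieces <- lapply(names(genome), function(ch) {
    l <- len[chrom == ch]
    if (length(l) == 0L) return(NULL)
    free <- genome[[ch]] - sum(l)
    if (free <= 0) {
      stop("infeasible coverage: intervals assigned to ", ch,
           " exceed its length")
    }
    offs <- sort(stats::runif(length(l), 0, free))
    start <- floor(offs) + cumsum(c(0, l[-length(l)])) + 1
    GenomicRanges::GRanges(ch, IRanges::IRanges(start = start, width = l))
  })
  gr <- suppressWarnings(
    do.call(c, pieces[!vapply(pieces, is.null, logical(1))]))
  names(gr) <- paste0(label, "_", seq_along(gr))
  S4Vectors::metadata(gr) <- list(label = label, role = "annotation")
  gr
}

# Place members of given lengths uniformly on the genome (starts uniform per
# chromosome chosen proportionally to length).
place_uniform <- function(lens, genome) {
  total <- sum(genome)
  chrom <- sample(names(genome), length(lens), replace = TRUE,
                  prob = genome / total)
  chrom_len <- unname(genome[chrom])
  lens <- pmin(lens, chrom_len)
  max_start <- chrom_len - lens + 1
  start <- floor(stats::runif(length(lens)) * max_start) + 1
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, width = lens))
}

# Two-mode placement against a target region set: with probability p the
# member starts inside a uniformly chosen target interval (>= 1 nt overlap
# guaranteed); otherwise it is placed entirely inside the complement, so
# P(overlap target) = p exactly.
place_two_mode <- function(lens, genome, target, p) {
  n <- length(lens)
  hit <- stats::runif(n) < p
  chrom <- character(n)
  start <- numeric(n)

  if (any(hit)) {
    iv <- sample.int(length(target), sum(hit), replace = TRUE)
    chrom[hit] <- as.character(GenomicRanges::seqnames(target))[iv]
    start[hit] <- GenomicRanges::start(target)[iv] +
      floor(stats::runif(sum(hit)) * GenomicRanges::width(target)[iv])
  }
  if (any(!hit)) {
    gaps <- GenomicRanges::setdiff(genome_granges(genome),
                                   GenomicRanges::reduce(target),
                                   ignore.strand = TRUE)
    gw <- GenomicRanges::width(gaps)
    gs <- GenomicRanges::start(gaps)
    gchr <- as.character(GenomicRanges::seqnames(gaps))
    for (i in which(!hit)) {
      pos <- gw - lens[i] + 1
      pos[pos < 0] <- 0
      tot <- sum(pos)
      if (tot <= 0) {
        # no gap can hold the member whole; truncate into the largest gap
        g <- which.max(gw)
        chrom[i] <- gchr[g]
        start[i] <- gs[g]
        lens[i] <- gw[g]
      } else {
        u <- floor(stats::runif(1) * tot)  # 0-based position among all slots
        g <- findInterval(u, cumsum(pos)) + 1L
        off <- u - c(0, cumsum(pos))[g]
        chrom[i] <- gchr[g]
        start[i] <- gs[g] + off
      }
    }
  }
  chrom_len <- unname(genome[chrom])
  end <- pmin(start + lens - 1, chrom_len)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start, end = end))
}

#' Generate a query class, optionally with a planted effect
#'
#' Without an effect, members are placed uniformly on the genome. With an
#' effect, the probability that a member overlaps the designated track is
#' `multiplier * coverage(track)`, clipped to 1 (with a warning): members
#' designated as overlapping start inside a randomly chosen track interval,
#' the rest are placed entirely within the track's complement, so the
#' planted rate is exact.
#'
#' @param genome Named numeric vector of chromosome lengths.
#' @param size Number of members.
#' @param min_len,mean_len,max_len Member length distribution (log-normal,
#'   clamped to `[min_len, max_len]`).
#' @param label Class label.
#' @param effect `NULL`, or a list with `track` (annotation `GRanges`) and
#'   `multiplier` (> 0; 1 plants the track's own coverage rate).
#' @return A query `GRanges` with named members.
#' @export
generate_class <- function(genome, size, min_len, mean_len, max_len,
                           label = "class", effect = NULL) {
  stopifnot(size >= 1)
  lens <- rlnorm_lengths(size, min_len, mean_len, max_len)
  gr <- if (is.null(effect)) {
    place_uniform(lens, genome)
  } else {
    stopifnot(is.list(effect), methods::is(effect$track, "GRanges"),
              is.numeric(effect$multiplier), effect$multiplier > 0)
    cov <- sum(GenomicRanges::width(GenomicRanges::reduce(effect$track))) /
      sum(genome)
    p <- effect$multiplier * cov
    if (p > 1) {
      warning(sprintf(
        "planted overlap rate %.3f for class '%s' exceeds 1; clipped", p, label))
      p <- 1
    }
    place_two_mode(lens, genome, effect$track, p)
  }
  names(gr) <- paste0(label, "_", seq_along(gr))
  S4Vectors::metadata(gr) <- list(label = label, role = "query")
  gr
}

#' Declare a synthetic study
#'
#' @param genome Named numeric vector of chromosome lengths (nt).
#' @param classes Data.frame: `label`, `size`, `min_len`, `mean_len`,
#'   `max_len`.
#' @param tracks Data.frame: `label`, `n_intervals`, `coverage`.
#' @param effects Optional data.frame: `class`, `track`, `multiplier`
#'   (at most one planted track per class; absent pairs are null,
#'   multiplier 1).
#' @param seed Integer master seed.
#' @return A `study_spec` list.
#' @export
study_spec <- function(genome, classes, tracks, effects = NULL, seed = 1L) {
  stopifnot(is.numeric(genome), !is.null(names(genome)),
            all(c("label", "size", "min_len", "mean_len", "max_len") %in%
                  names(classes)),
            all(c("label", "n_intervals", "coverage") %in% names(tracks)),
            all(classes$size >= 1), all(tracks$coverage > 0 & tracks$coverage < 1))
  if (!is.null(effects)) {
    stopifnot(all(c("class", "track", "multiplier") %in% names(effects)),
              all(effects$multiplier > 0))
    if (!all(effects$class %in% classes$label)) stop("effect references unknown class")
    if (!all(effects$track %in% tracks$label)) stop("effect references unknown track")
    if (anyDuplicated(effects$class)) {
      stop("at most one planted track per class is supported")
    }
  }
  structure(list(genome = genome, classes = classes, tracks = tracks,
                 effects = effects, seed = as.integer(seed)),
            class = "study_spec")
}

#' Default study specification shaped like a 15-class ncRNA analysis
#'
#' Fifteen classes with the member counts and length ranges of
#' [ncrna_class_catalog()] against `n_tracks` tracks with coverages spread
#' over 0.05-0.35 of a 50 Mb two-chromosome synthetic genome. When
#' `plant_effects = TRUE` each class is planted against one track,
#' alternating enrichment (x2) and depletion (x0.5).
#'
#' @param n_tracks Number of annotation tracks (default 40).
#' @param seed Integer master seed.
#' @param genome Named chromosome lengths (default two chromosomes, 50 Mb).
#' @param plant_effects Plant one effect per class (default `TRUE`).
#' @return A `study_spec`.
#' @export
ncrna_study_spec <- function(n_tracks = 40L, seed = 1L,
                             genome = c(chrS1 = 3e7, chrS2 = 2e7),
                             plant_effects = TRUE) {
  cat <- ncrna_class_catalog()
  coverage <- round(seq(0.05, 0.35, length.out = n_tracks), 4)
  tracks <- data.frame(
    label = sprintf("track%02d", seq_len(n_tracks)),
    n_intervals = pmax(200L, as.integer(round(coverage * sum(genome) / 4000))),
    coverage = coverage,
    stringsAsFactors = FALSE
  )
  effects <- if (plant_effects) {
    data.frame(
      class = cat$label,
      track = tracks$label[((seq_len(nrow(cat)) - 1L) %% n_tracks) + 1L],
      multiplier = ifelse(seq_len(nrow(cat)) %% 2L == 0L, 2, 0.5),
      stringsAsFactors = FALSE
    )
  } else NULL
  study_spec(genome, cat, tracks, effects, seed)
}

#' Generate a full synthetic study
#'
#' Generates all tracks then all classes under the spec's master seed, audits
#' the realized per-(class, track) overlap rates, and optionally writes the
#' study to disk as BED files plus a tab-separated truth manifest.
#' Regeneration from the same spec is byte-identical.
#'
#' @param spec A `study_spec`.
#' @param output_dir Optional directory; creates `queries/`, `annotations/`
#'   and `truth.tsv` inside it.
#' @return A `synthetic_study` list: `classes` and `tracks` (named lists of
#'   `GRanges`), `truth` (data.frame with `class`, `track`, `multiplier`,
#'   `target_rate`, `realized_rate`), `spec`.
#' @export
generate_study <- function(spec, output_dir = NULL) {
  stopifnot(inherits(spec, "study_spec"))
  set.seed(spec$seed)
  tracks <- stats::setNames(lapply(seq_len(nrow(spec$tracks)), function(j) {
    generate_track(spec$genome, spec$tracks$n_intervals[j],
                   spec$tracks$coverage[j], label = spec$tracks$label[j])
  }), spec$tracks$label)

  classes <- stats::setNames(lapply(seq_len(nrow(spec$classes)), function(i) {
    cl <- spec$classes[i, ]
    eff <- NULL
    if (!is.null(spec$effects)) {
      e <- spec$effects[spec$effects$class == cl$label, , drop = FALSE]
      if (nrow(e) == 1L) {
        eff <- list(track = tracks[[e$track]], multiplier = e$multiplier)
      }
    }
    generate_class(spec$genome, cl$size, cl$min_len, cl$mean_len, cl$max_len,
                   label = cl$label, effect = eff)
  }), spec$classes$label)

  truth <- do.call(rbind, lapply(names(classes), function(cn) {
    do.call(rbind, lapply(names(tracks), function(tn) {
      mult <- 1
      target <- NA_real_
      if (!is.null(spec$effects)) {
        e <- spec$effects[spec$effects$class == cn & spec$effects$track == tn, ]
        if (nrow(e) == 1L) {
          cov <- sum(GenomicRanges::width(GenomicRanges::reduce(tracks[[tn]]))) /
            sum(spec$genome)
          mult <- e$multiplier
          target <- min(1, mult * cov)
        }
      }
      data.frame(class = cn, track = tn, multiplier = mult,
                 target_rate = target,
                 realized_rate = mean(overlaps_any(classes[[cn]], tracks[[tn]])),
                 stringsAsFactors = FALSE)
    }))
  }))

  if (!is.null(output_dir)) {
    qd <- file.path(output_dir, "queries")
    ad <- file.path(output_dir, "annotations")
    dir.create(qd, recursive = TRUE, showWarnings = FALSE)
    dir.create(ad, recursive = TRUE, showWarnings = FALSE)
    for (cn in names(classes)) write_bed(classes[[cn]], file.path(qd, paste0(cn, ".bed")))
    for (tn in names(tracks)) write_bed(tracks[[tn]], file.path(ad, paste0(tn, ".bed")))
    utils::write.table(truth, file.path(output_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(classes = classes, tracks = tracks, truth = truth,
                 spec = spec),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d classes (%d members) x %d tracks\n",
              length(x$classes), sum(vapply(x$classes, length, integer(1))),
              length(x$tracks)))
  if (!is.null(x$spec) && !is.null(x$spec$effects)) {
    cat(sprintf("  planted effects: %d\n", nrow(x$spec$effects)))
  }
  invisible(x)
}

#' Shared-state synthetic study with correlated track groups
#'
#' Emulates correlated chromatin-state tracks: the genome is tiled into
#' segments assigned to one of two latent states (or neither); each track in
#' a group is an independent noisy subsample of its state's segments, so
#' tracks within a group are strongly correlated. Each class group is
#' planted to prefer one latent state, so the two class groups show opposite
#' enrichment signs across the two track groups and the class dendrogram
#' should bipartition by group.
#'
#' @param seed Integer master seed.
#' @param genome Named chromosome lengths (default one 20 Mb chromosome).
#' @param n_tracks_per_group,n_classes_per_group Group sizes.
#' @param class_size Members per class (default 300).
#' @param multiplier Planted overlap-rate multiplier vs the latent state
#'   coverage (default 2.5).
#' @param segment_len Latent segment length in nt (default 20 kb).
#' @param state_fraction Genome fraction per latent state (default 0.25).
#' @param keep_frac Probability a track keeps a segment of its state
#'   (default 0.7).
#' @return A `synthetic_study` whose `truth` carries `class_group` and
#'   `track_group` columns, plus `latent` region sets.
#' @export
shared_state_study <- function(seed = 1L, genome = c(chrS1 = 2e7),
                               n_tracks_per_group = 6L,
                               n_classes_per_group = 3L,
                               class_size = 300L, multiplier = 2.5,
                               segment_len = 2e4, state_fraction = 0.25,
                               keep_frac = 0.7) {
  stopifnot(state_fraction > 0, state_fraction < 0.5)
  set.seed(seed)
  tiles <- unlist(GenomicRanges::tile(genome_granges(genome),
                                      width = segment_len))
  state <- sample(c(1L, 2L, 0L), length(tiles), replace = TRUE,
                  prob = c(state_fraction, state_fraction,
                           1 - 2 * state_fraction))
  latent <- list(GenomicRanges::reduce(tiles[state == 1L]),
                 GenomicRanges::reduce(tiles[state == 2L]))

  make_track <- function(state_gr, label) {
    segs <- state_gr[stats::runif(length(state_gr)) < keep_frac]
    w <- GenomicRanges::width(segs)
    frac <- stats::runif(length(segs), 0.5, 1)
    w2 <- pmax(1, round(w * frac))
    off <- floor(stats::runif(length(segs)) * (w - w2 + 1))
    gr <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(segs),
      IRanges::IRanges(start = GenomicRanges::start(segs) + off, width = w2))
    names(gr) <- paste0(label, "_", seq_along(gr))
    S4Vectors::metadata(gr) <- list(label = label, role = "annotation")
    gr
  }

  tracks <- list()
  track_group <- integer(0)
  for (g in 1:2) {
    for (t in seq_len(n_tracks_per_group)) {
      lab <- sprintf("g%dtrack%02d", g, t)
      tracks[[lab]] <- make_track(latent[[g]], lab)
      track_group[lab] <- g
    }
  }

  classes <- list()
  class_group <- integer(0)
  for (g in 1:2) {
    for (cidx in seq_len(n_classes_per_group)) {
      lab <- sprintf("g%dclass%d", g, cidx)
      lens <- rlnorm_lengths(class_size, 30, 120, 500)
      cov <- sum(GenomicRanges::width(latent[[g]])) / sum(genome)
      gr <- place_two_mode(lens, genome, latent[[g]],
                           min(1, multiplier * cov))
      names(gr) <- paste0(lab, "_", seq_along(gr))
      S4Vectors::metadata(gr) <- list(label = lab, role = "query")
      classes[[lab]] <- gr
      class_group[lab] <- g
    }
  }

  truth <- expand.grid(class = names(classes), track = names(tracks),
                       stringsAsFactors = FALSE)
  truth$class_group <- class_group[truth$class]
  truth$track_group <- track_group[truth$track]
  truth$realized_rate <- mapply(function(cn, tn) {
    mean(overlaps_any(classes[[cn]], tracks[[tn]]))
  }, truth$class, truth$track)

  structure(list(classes = classes, tracks = tracks, truth = truth,
                 latent = latent, class_group = class_group,
                 track_group = track_group, seed = seed),
            class = "synthetic_study")
}
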