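# End-to-end orchestration: read query/annotation BED collections, run the
# enrichment analysis, assemble/filter the score matrix, cluster, correlate,
# and write deterministic outputs plus a checksummed run manifest.

#' Build a validated run configuration
#'
#' @param query_dir Directory of query BED files (one per class).
#' @param annotation_dir Directory of annotation BED files (one per track).
#' @param output_dir Directory for results (created if needed).
#' @param n_samplings Random samplings per (class, track) pair (default
#'   1000).
#' @param alpha Significance cutoff for the presence filter and the
#'   correlation track subset (default 0.01).
#' @param sd_min Score-SD filter threshold (default 2.0).
#' @param bh_scope `"per_class"` or `"global"` BH correction.
#' @param seed Master integer seed.
#' @param min_p Floor for adjusted p-values before the log transform.
#' @param chisq_kind,correct Chi-square options, see [chi_square_test()].
#' @param variability_exclude Class labels excluded from the second
#'   size-vs-SD correlation.
#' @return A `run_config` list.
#' @export
run_config <- function(query_dir, annotation_dir, output_dir,
                       n_samplings = 1000L, alpha = 0.01, sd_min = 2.0,
                       bh_scope = c("per_class", "global"), seed = 1L,
                       min_p = 1e-300,
                       chisq_kind = c("independence", "gof"),
                       correct = FALSE,
                       variability_exclude = character()) {
  bh_scope <- match.arg(bh_scope)
  chisq_kind <- match.arg(chisq_kind)
  stopifnot(n_samplings >= 1, alpha > 0, alpha < 1, sd_min >= 0)
  structure(
    list(query_dir = query_dir, annotation_dir = annotation_dir,
         output_dir = output_dir, n_samplings = as.integer(n_samplings),
         alpha = alpha, sd_min = sd_min, bh_scope = bh_scope,
         seed = as.integer(seed), min_p = min_p, chisq_kind = chisq_kind,
         correct = correct, variability_exclude = variability_exclude),
    class = "run_config"
  )
}

list_bed_files <- function(dir) {
  sort(list.files(dir, pattern = "\\.bed(\\.gz)?$", full.names = TRUE))
}

# Lenient single-file scan used by validate_inputs(): records malformed
# lines instead of aborting.
scan_bed <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)
  keep <- !grepl("^(track\\b|browser\\b|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  chroms <- character(0)
  bad <- data.frame(line = integer(0), reason = character(0),
                    stringsAsFactors = FALSE)
  n_ok <- 0L
  if (length(lines)) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      reason <- NULL
      if (length(f) < 3L) reason <- "fewer than 3 fields"
      else if (!grepl("^[0-9]+$", f[2L]) || !grepl("^[0-9]+$", f[3L])) {
        reason <- "non-integer coordinates"
      } else if (as.numeric(f[2L]) >= as.numeric(f[3L])) {
        reason <- "start >= end"
      }
      if (is.null(reason)) {
        n_ok <- n_ok + 1L
        chroms <- c(chroms, f[1L])
      } else {
        bad <- rbind(bad, data.frame(line = line_no[i], reason = reason,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  list(n_ok = n_ok, chroms = unique(chroms), malformed = bad)
}

#' Validate pipeline inputs without running the analysis
#'
#' Reports per-file interval counts, malformed records (non-integer
#' coordinates, start >= end, short lines) and chromosome names present in
#' queries but absent from annotations (names are compared as exact strings,
#' so `"1"` and `"chr1"` do not match). Report only; never errors on file
#' content.
#'
#' @param config A `run_config`.
#' @return A list: `files` (data.frame file/role/n_intervals/n_malformed),
#'   `malformed` (data.frame file/line/reason), `warnings` (character).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "run_config"))
  qf <- list_bed_files(config$query_dir)
  af <- list_bed_files(config$annotation_dir)
  scan_all <- function(paths, role) {
    lapply(paths, function(p) c(list(file = p, role = role), scan_bed(p)))
  }
  scans <- c(scan_all(qf, "query"), scan_all(af, "annotation"))
  files <- do.call(rbind, lapply(scans, function(s) {
    data.frame(file = s$file, role = s$role, n_intervals = s$n_ok,
               n_malformed = nrow(s$malformed), stringsAsFactors = FALSE)
  }))
  malformed <- do.call(rbind, lapply(scans, function(s) {
    if (nrow(s$malformed) == 0L) return(NULL)
    cbind(data.frame(file = s$file, stringsAsFactors = FALSE), s$malformed)
  }))
  if (is.null(malformed)) {
    malformed <- data.frame(file = character(0), line = integer(0),
                            reason = character(0), stringsAsFactors = FALSE)
  }
  q_chroms <- unique(unlist(lapply(scans[seq_along(qf)], `[[`, "chroms")))
  a_chroms <- unique(unlist(lapply(scans[length(qf) + seq_along(af)],
                                   `[[`, "chroms")))
  warnings <- character(0)
  orphan <- setdiff(q_chroms, a_chroms)
  if (length(af) && length(orphan)) {
    warnings <- sprintf(
      "query chromosome '%s' is absent from all annotation tracks", orphan)
  }
  if (length(qf) == 0L) warnings <- c(warnings, "no query BED files found")
  if (length(af) == 0L) warnings <- c(warnings, "no annotation BED files found")
  list(files = files, malformed = malformed, warnings = warnings)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full enrichment-and-classification pipeline
#'
#' Stages: read BED collections; per-pair enrichment against the pooled
#' sampled null; matrix assembly; class variability; presence + SD track
#' filtering; Ward/Chebyshev clustering of the filtered matrix (rows and
#' columns) with Newick and heatmap export; Pearson correlation of class
#' profiles over presence-filtered tracks with the best-partner table.
#' Clustering and correlation are skipped with a logged notice when the
#' surviving matrix is too small. All outputs are tab-separated (or Newick /
#' PNG) and a `manifest.json` records the configuration, package version,
#' notices and an MD5 checksum per output file. Identical config and seed
#' give byte-identical tables.
#'
#' @param config A `run_config`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  qf <- list_bed_files(config$query_dir)
  af <- list_bed_files(config$annotation_dir)
  if (length(qf) == 0L) stop("no query BED files in ", config$query_dir)
  if (length(af) == 0L) stop("no annotation BED files in ", config$annotation_dir)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  notices <- character(0)
  out <- function(f) file.path(config$output_dir, f)
  produced <- character(0)
  add_file <- function(f) produced <<- c(produced, f)

  classes <- run_stage("read_queries", {
    cl <- lapply(qf, read_bed, role = "query")
    stats::setNames(cl, vapply(cl, function(g) S4Vectors::metadata(g)$label, ""))
  })
  tracks <- run_stage("read_annotations", {
    tr <- lapply(af, read_bed, role = "annotation")
    stats::setNames(tr, vapply(tr, function(g) S4Vectors::metadata(g)$label, ""))
  })

  results <- run_stage("enrichment", enrich_classes(
    classes, tracks, n_samplings = config$n_samplings, seed = config$seed,
    bh_scope = config$bh_scope, min_p = config$min_p,
    chisq_kind = config$chisq_kind, correct = config$correct))
  run_stage("write_enrichment", {
    write_enrichment_table(results, out("enrichment.tsv"))
    add_file("enrichment.tsv")
  })

  em <- run_stage("assemble_matrix", assemble_matrix(results))
  run_stage("write_matrices", {
    write_matrix_tsv(em$scores, out("matrix_scores.tsv"))
    write_matrix_tsv(em$p_adj, out("matrix_padj.tsv"))
    write_matrix_tsv(em$directions, out("matrix_directions.tsv"))
    add_file("matrix_scores.tsv"); add_file("matrix_padj.tsv")
    add_file("matrix_directions.tsv")
  })

  variability <- NULL
  if (length(em$track_labels) >= 2L) {
    variability <- run_stage("class_variability", class_variability(
      em, sizes = vapply(classes, length, numeric(1)),
      exclude = config$variability_exclude))
    run_stage("write_variability", {
      utils::write.table(variability$table, out("variability.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      add_file("variability.tsv")
    })
  } else {
    notices <- c(notices, "class variability skipped: fewer than 2 tracks")
  }

  fm <- run_stage("filter_tracks",
                  filter_tracks(em, alpha = config$alpha,
                                sd_min = config$sd_min))
  run_stage("write_filtered", {
    write_matrix_tsv(fm$scores, out("matrix_filtered.tsv"))
    add_file("matrix_filtered.tsv")
  })

  if (length(fm$class_labels) >= 2L && length(fm$track_labels) >= 2L) {
    run_stage("clustering", {
      row_hc <- ward_linkage(chebyshev_distances(fm$scores, "rows"))
      col_hc <- ward_linkage(chebyshev_distances(fm$scores, "columns"))
      export_newick(row_hc, out("class_dendrogram.nwk"))
      export_newick(col_hc, out("track_dendrogram.nwk"))
      add_file("class_dendrogram.nwk"); add_file("track_dendrogram.nwk")
      heatmap_export(fm, row_hc, col_hc, out("heatmap.png"),
                     table_path = out("heatmap_table.tsv"))
      add_file("heatmap_table.tsv")
    })
  } else {
    msg <- sprintf(
      "clustering skipped: filtered matrix is %d x %d (need at least 2 x 2)",
      length(fm$class_labels), length(fm$track_labels))
    notices <- c(notices, msg)
    message(msg)
  }

  n_sig_tracks <- sum(apply(em$p_adj, 2L, min) < config$alpha)
  if (length(em$class_labels) >= 2L && n_sig_tracks >= 3L) {
    run_stage("correlation", {
      corr <- pearson_profiles(em, tracks = "significant",
                               alpha = config$alpha)
      write_matrix_tsv(corr$r, out("correlation.tsv"))
      add_file("correlation.tsv")
      partners <- best_partners(corr)
      utils::write.table(partners, out("partners.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      add_file("partners.tsv")
    })
  } else {
    msg <- sprintf(
      "correlation skipped: %d classes, %d significant tracks (need >= 2 and >= 3)",
      length(em$class_labels), n_sig_tracks)
    notices <- c(notices, msg)
    message(msg)
  }

  manifest <- run_stage("manifest", {
    files <- lapply(produced, function(f) {
      list(file = f, md5 = unname(tools::md5sum(out(f))))
    })
    m <- list(
      package = "epicoloc",
      version = as.character(utils::packageVersion("epicoloc")),
      config = unclass(config),
      n_classes = length(classes),
      n_tracks = length(tracks),
      n_tracks_filtered = length(fm$track_labels),
      n_tracks_significant = n_sig_tracks,
      size_sd_cor = if (!is.null(variability)) variability$size_sd_cor else NULL,
      notices = notices,
      files = files
    )
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    m
  })
  invisible(manifest)
}
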