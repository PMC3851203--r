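# Genomic interval data model: BED I/O and overlap-query indexing.
#
# Intervals are held as GRanges (1-based, closed), the standard Bioconductor
# container; BED files are 0-based half-open, so coordinates are shifted by
# one on read/write. Overlap of >= 1 nt in BED space is exactly GRanges
# overlap, strand ignored.

#' Read a BED file into a region set
#'
#' Parses BED3-BED6 (tab-separated; `track`, `browser`, `#` comment and blank
#' lines are skipped) into a `GRanges`. Gzip-compressed files are read
#' transparently. Unnamed records (missing or `"."` name field) are named
#' `<label>_<line>`; duplicated names are auto-suffixed to keep them unique
#' within the set. Strand is kept (`.` maps to `*`) but is ignored by all
#' overlap operations in this package.
#'
#' @param path Path to a BED or BED.gz file.
#' @param label Set label; defaults to the file name without extension.
#' @param role One of `"query"` or `"annotation"`, stored as metadata.
#' @return A `GRanges` with `metadata()` fields `label` and `role`. An empty
#'   file yields an empty `GRanges`.
#' @details Malformed records (fewer than 3 fields, non-integer coordinates,
#'   start >= end, negative start) raise an error naming the offending line
#'   number. Zero-length intervals are rejected.
#' @examples
#' p <- tempfile(fileext = ".bed")
#' writeLines("chr1\t10\t20\tx\t0\t+", p)
#' rs <- read_bed(p)
#' GenomicRanges::width(rs)  # 10
#' @export
read_bed <- function(path, label = NULL, role = c("query", "annotation")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(label)) {
    label <- sub("\\.bed(\\.gz)?$", "", basename(path), ignore.case = TRUE)
  }
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)

  keep <- !grepl("^(track\\b|browser\\b|#)", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]

  if (length(lines) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::metadata(gr) <- list(label = label, role = role, source = path)
    return(gr)
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- line_no[which(nf < 3L)[1L]]
    stop(sprintf("%s: line %d: BED record has fewer than 3 tab-separated fields",
                 path, bad))
  }

  chrom <- vapply(fields, `[[`, "", 1L)
  start_chr <- vapply(fields, `[[`, "", 2L)
  end_chr <- vapply(fields, `[[`, "", 3L)
  ok_int <- grepl("^[0-9]+$", start_chr) & grepl("^[0-9]+$", end_chr)
  if (any(!ok_int)) {
    bad <- line_no[which(!ok_int)[1L]]
    stop(sprintf("%s: line %d: non-integer BED coordinates", path, bad))
  }
  start0 <- as.numeric(start_chr)
  end0 <- as.numeric(end_chr)
  if (any(start0 >= end0)) {
    bad <- line_no[which(start0 >= end0)[1L]]
    stop(sprintf("%s: line %d: start >= end (zero-length intervals are invalid)",
                 path, bad))
  }

  nm <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), ".")
  nm[nm == "." | !nzchar(nm)] <- paste0(label, "_", line_no[nm == "." | !nzchar(nm)])
  nm <- make.unique(nm, sep = "_")

  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"

  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand
  )
  names(gr) <- nm
  S4Vectors::metadata(gr) <- list(label = label, role = role, source = path)
  gr
}

#' Write a region set as BED6
#'
#' Writes `chrom start end name 0 strand` with BED 0-based half-open
#' coordinates; strand `*` is written as `.`. The round trip through
#' [read_bed()] preserves coordinates, names and strand.
#'
#' @param regions A `GRanges` (as from [read_bed()] or the generators).
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  nm <- names(regions)
  if (is.null(nm)) nm <- paste0("region_", seq_along(regions))
  strand <- as.character(GenomicRanges::strand(regions))
  strand[strand == "*"] <- "."
  lines <- if (length(regions) == 0L) character(0) else sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    as.character(GenomicRanges::seqnames(regions)),
    GenomicRanges::start(regions) - 1L,
    GenomicRanges::end(regions),
    nm, strand
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con), add = TRUE)
  tryCatch(writeLines(lines, con),
           error = function(e) stop("failed to write BED file ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Build an overlap-query index over an annotation region set
#'
#' Wraps the annotation in a nested containment list (`GNCList`) for fast
#' repeated overlap queries. Querying a chromosome absent from the annotation
#' returns no hits; chromosome names are compared as exact strings.
#'
#' @param annotation A `GRanges` of annotation intervals.
#' @return An `interval_index` object.
#' @export
build_index <- function(annotation) {
  stopifnot(methods::is(annotation, "GRanges"))
  structure(
    list(
      granges = annotation,
      label = S4Vectors::metadata(annotation)$label %||% "annotation",
      nclist = GenomicRanges::GNCList(annotation)
    ),
    class = "interval_index"
  )
}

#' @export
print.interval_index <- function(x, ...) {
  cat(sprintf("<interval_index> '%s': %d intervals on %d sequence(s)\n",
              x$label, length(x$granges),
              length(unique(as.character(GenomicRanges::seqnames(x$granges))))))
  invisible(x)
}

as_index_granges <- function(index) {
  if (inherits(index, "interval_index")) index$nclist
  else if (methods::is(index, "GRanges")) index
  else stop("expected an interval_index or GRanges annotation")
}

#' Query an index for annotation intervals overlapping a region
#'
#' @param index An `interval_index` from [build_index()].
#' @param query A `GRanges` of one or more query intervals.
#' @return The annotation intervals sharing at least 1 nt with any query
#'   interval (strand ignored).
#' @export
query_index <- function(index, query) {
  stopifnot(inherits(index, "interval_index"))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(query, index$nclist, ignore.strand = TRUE))
  index$granges[sort(unique(S4Vectors::subjectHits(hits)))]
}

#' Which query members overlap any annotation interval?
#'
#' @param query A `GRanges` of query intervals.
#' @param index An `interval_index` or annotation `GRanges`.
#' @return Logical vector, one entry per query member: `TRUE` if the member
#'   shares at least 1 nt with at least one annotation interval.
#' @export
overlaps_any <- function(query, index) {
  suppressWarnings(
    GenomicRanges::countOverlaps(query, as_index_granges(index),
                                 ignore.strand = TRUE)) > 0
}

`%||%` <- function(a, b) if (is.null(a)) b else a
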