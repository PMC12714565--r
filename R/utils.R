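# Internal interval helpers. All coordinates in this package are 0-based
# half-open (BED convention): start inclusive, end exclusive, length = end - start.

#' Test whether two genomic intervals overlap
#'
#' Half-open overlap test: two intervals share at least one base iff they are
#' on the same chromosome and `start_a < end_b && start_b < end_a`. Touching
#' intervals (`end_a == start_b`) do not overlap. Vectorized over all
#' arguments.
#'
#' @param chrom_a,start_a,end_a First interval (0-based half-open).
#' @param chrom_b,start_b,end_b Second interval.
#' @return Logical vector.
#' @examples
#' interval_overlaps("chr1", 0, 10, "chr1", 10, 20)  # FALSE: touching only
#' interval_overlaps("chr1", 0, 10, "chr1", 9, 20)   # TRUE: one shared bp
#' @export
interval_overlaps <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  chrom_a == chrom_b & start_a < end_b & start_b < end_a
}

# validate a tibble of intervals with columns chrom/start/end (possibly
# prefixed); aborts with the offending rows.
check_intervals <- function(df, start_col = "start", end_col = "end",
                            what = "interval") {
  s <- df[[start_col]]
  e <- df[[end_col]]
  bad <- which(!is.finite(s) | !is.finite(e) | s < 0 | s >= e)
  if (length(bad) > 0) {
    abort(sprintf(
      "invalid %s coordinates (need 0 <= start < end) at row(s): %s",
      what, paste(head(bad, 5L), collapse = ", ")
    ))
  }
  invisible(df)
}

# 0-based half-open tibble -> GRanges (1-based closed); levels fixes the
# seqlevel universe so disjoint chromosome sets compare without noise
intervals_to_granges <- function(df, chrom_col = "chrom",
                                 start_col = "start", end_col = "end",
                                 levels = NULL) {
  chrom <- df[[chrom_col]]
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = levels %||% unique(chrom)),
    ranges = IRanges::IRanges(start = df[[start_col]] + 1L, end = df[[end_col]])
  )
}

# all overlapping pairs (>= 1 shared bp) between two interval tibbles;
# returns tibble(x_idx, y_idx). Empty inputs give zero rows.
overlap_join <- function(x, y, x_cols = c("chrom", "start", "end"),
                         y_cols = c("chrom", "start", "end")) {
  if (nrow(x) == 0 || nrow(y) == 0) {
    return(tibble(x_idx = integer(), y_idx = integer()))
  }
  lv <- union(unique(x[[x_cols[1]]]), unique(y[[y_cols[1]]]))
  gx <- intervals_to_granges(x, x_cols[1], x_cols[2], x_cols[3], levels = lv)
  gy <- intervals_to_granges(y, y_cols[1], y_cols[2], y_cols[3], levels = lv)
  hits <- GenomicRanges::findOverlaps(gx, gy, minoverlap = 1L)
  tibble(
    x_idx = S4Vectors::queryHits(hits),
    y_idx = S4Vectors::subjectHits(hits)
  )
}

# size-safe sample: never interprets a length-1 x as 1:x
resample <- function(x, n) x[sample.int(length(x), n, replace = TRUE)]
resample_noreplace <- function(x, n) x[sample.int(length(x), n)]

# derive a reproducible sub-seed for a named generator stage from the master
# seed, so adding a stage never perturbs draws in earlier stages. Kept below
# .Machine$integer.max.
stage_seed <- function(seed, stage) {
  offsets <- c(
    tracks = 101L, loops = 211L, reads = 307L,
    ct = 401L, image = 503L
  )
  if (!stage %in% names(offsets)) {
    abort(paste0("unknown generator stage: ", stage))
  }
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}
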