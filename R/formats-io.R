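# Readers and writers for the tabular genomic formats the pipeline consumes.
# Every coordinate is 0-based half-open, the native convention of narrowPeak,
# BED and BEDPE, and the internal convention of this package.

np_cols <- c(
  "chrom", "start", "end", "name", "score", "strand",
  "signal_value", "neglog10_p", "neglog10_q", "summit_offset"
)

#' Read a MACS2 narrowPeak file
#'
#' Parses the 10-column narrowPeak dialect into a tibble, one row per peak.
#' Lines starting with `#` or `track` are skipped. Column 8 is interpreted as
#' -log10(P) (MACS2 semantics) unless `neglog10_p_col` points elsewhere; peak
#' significance filtering downstream operates on this column.
#'
#' @param path Path to a narrowPeak file.
#' @param neglog10_p_col 1-based column index holding -log10(P). Default 8,
#'   the MACS2 convention. Exposed because "log P" conventions vary between
#'   peak callers.
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   `name`, `score`, `strand`, `signal_value`, `neglog10_p`, `neglog10_q`
#'   (-1 when unset), `summit_offset` (-1 when unset), in file order.
#' @seealso [write_narrowpeak()], [filter_peaks()]
#' @export
read_narrowpeak <- function(path, neglog10_p_col = 8L) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track)", lines) & nzchar(lines)
  data_lines <- lines[keep]
  line_nos <- which(keep)
  if (length(data_lines) == 0) {
    return(tibble(
      chrom = character(), start = integer(), end = integer(),
      name = character(), score = integer(), strand = character(),
      signal_value = double(), neglog10_p = double(), neglog10_q = double(),
      summit_offset = integer()
    ))
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 10L)) {
    bad <- line_nos[which(nf < 10L)[1]]
    abort(sprintf("malformed narrowPeak line %d: fewer than 10 tab-separated fields", bad))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  suppressWarnings(peaks <- tibble(
    chrom = col(1),
    start = as.integer(col(2)),
    end = as.integer(col(3)),
    name = col(4),
    score = as.integer(col(5)),
    strand = col(6),
    signal_value = as.double(col(7)),
    neglog10_p = as.double(col(neglog10_p_col)),
    neglog10_q = as.double(col(9)),
    summit_offset = as.integer(col(10))
  ))
  num_bad <- which(is.na(peaks$start) | is.na(peaks$end) | is.na(peaks$neglog10_p))
  if (length(num_bad) > 0) {
    abort(sprintf("malformed narrowPeak line %d: non-numeric coordinate or statistic", line_nos[num_bad[1]]))
  }
  coord_bad <- which(peaks$start < 0 | peaks$start >= peaks$end)
  if (length(coord_bad) > 0) {
    abort(sprintf("invalid peak interval on line %d: need 0 <= start < end", line_nos[coord_bad[1]]))
  }
  if (any(peaks$neglog10_p < 0)) {
    abort("negative -log10(P) encountered; narrowPeak column 8 must be non-negative")
  }
  bad_summit <- which(peaks$summit_offset != -1L &
    (peaks$summit_offset < 0L | peaks$summit_offset >= peaks$end - peaks$start))
  if (length(bad_summit) > 0) {
    abort(sprintf("summit offset outside peak on line %d", line_nos[bad_summit[1]]))
  }
  peaks
}

#' Write peaks to a narrowPeak file
#'
#' @param peaks Tibble as returned by [read_narrowpeak()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  check_intervals(peaks, what = "peak")
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%d",
    peaks$chrom, peaks$start, peaks$end, peaks$name, peaks$score, peaks$strand,
    format(peaks$signal_value, trim = TRUE, scientific = FALSE),
    format(peaks$neglog10_p, trim = TRUE, scientific = FALSE),
    format(peaks$neglog10_q, trim = TRUE, scientific = FALSE),
    peaks$summit_offset
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read chromatin loops from BEDPE or a hiccups loop list
#'
#' Reads loop anchor pairs, canonically orders the anchors, collapses exact
#' duplicate loops (identical anchor coordinates, e.g. the same loop reported
#' at two hiccups resolutions) into one record with a `multiplicity` count,
#' and flags inter-chromosomal and degenerate (self-overlapping anchor) calls.
#'
#' @param path One or more loop files; multiple files are pooled before
#'   deduplication.
#' @param dialect `"bedpe"` (headerless, first six columns
#'   chrom1/start1/end1/chrom2/start2/end2) or `"hiccups"` (Juicer hiccups
#'   loop list whose header line starts with `#` or `chr1` and whose extra
#'   statistic columns are passed through untouched in `attrs`).
#' @param chrom_map Optional named character vector normalizing chromosome
#'   names, e.g. `c("1" = "chr1")`. Applied only when supplied; names are
#'   never guessed.
#' @return A tibble with columns `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b` (anchors canonically ordered), `multiplicity`,
#'   `inter_chromosomal`, `degenerate`, `attrs` (tab-joined pass-through of
#'   extra columns, `NA` if none).
#' @export
read_loops <- function(path, dialect = c("bedpe", "hiccups"), chrom_map = NULL) {
  dialect <- match.arg(dialect)
  raw <- purrr::map(path, function(p) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
    lines <- readr::read_lines(p)
    lines <- lines[nzchar(lines)]
    if (dialect == "hiccups" && length(lines) > 0 &&
      grepl("^(#|chr1\\t|chromosome)", lines[1])) {
      lines <- lines[-1]
    }
    lines <- lines[!grepl("^(#|track)", lines)]
    lines
  })
  lines <- unlist(raw)
  if (length(lines) == 0) {
    return(empty_loops())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L)) {
    abort("malformed loop line: fewer than 6 tab-separated fields")
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  loops <- tibble(
    chrom_a = col(1), start_a = as.numeric(col(2)), end_a = as.numeric(col(3)),
    chrom_b = col(4), start_b = as.numeric(col(5)), end_b = as.numeric(col(6)),
    attrs = vapply(fields, function(f) {
      if (length(f) > 6L) paste(f[-(1:6)], collapse = "\t") else NA_character_
    }, character(1))
  )
  if (anyNA(loops$start_a) || anyNA(loops$start_b) ||
    anyNA(loops$end_a) || anyNA(loops$end_b)) {
    abort("malformed loop line: non-numeric anchor coordinate")
  }
  if (any(loops$start_a < 0 | loops$start_b < 0)) {
    abort("negative anchor coordinate in loop file")
  }
  if (!is.null(chrom_map)) {
    loops$chrom_a <- dplyr::coalesce(unname(chrom_map[loops$chrom_a]), loops$chrom_a)
    loops$chrom_b <- dplyr::coalesce(unname(chrom_map[loops$chrom_b]), loops$chrom_b)
  }
  canonicalize_loops(loops)
}

empty_loops <- function() {
  tibble(
    chrom_a = character(), start_a = double(), end_a = double(),
    chrom_b = character(), start_b = double(), end_b = double(),
    multiplicity = integer(), inter_chromosomal = logical(),
    degenerate = logical(), attrs = character()
  )
}

# order anchors (chrom, then start), flag inter-chromosomal/degenerate,
# collapse exact duplicates keeping the first record's attrs
canonicalize_loops <- function(loops) {
  swap <- (loops$chrom_a > loops$chrom_b) |
    (loops$chrom_a == loops$chrom_b & loops$start_a > loops$start_b)
  sw <- function(a, b) {
    tmp <- a
    a[swap] <- b[swap]
    b[swap] <- tmp[swap]
    list(a = a, b = b)
  }
  ch <- sw(loops$chrom_a, loops$chrom_b)
  st <- sw(loops$start_a, loops$start_b)
  en <- sw(loops$end_a, loops$end_b)
  loops$chrom_a <- ch$a
  loops$chrom_b <- ch$b
  loops$start_a <- st$a
  loops$start_b <- st$b
  loops$end_a <- en$a
  loops$end_b <- en$b
  loops$inter_chromosomal <- loops$chrom_a != loops$chrom_b
  loops$degenerate <- interval_overlaps(
    loops$chrom_a, loops$start_a, loops$end_a,
    loops$chrom_b, loops$start_b, loops$end_b
  )
  loops |>
    group_by(.data$chrom_a, .data$start_a, .data$end_a,
             .data$chrom_b, .data$start_b, .data$end_b) |>
    summarise(
      multiplicity = dplyr::n(),
      inter_chromosomal = .data$inter_chromosomal[1],
      degenerate = .data$degenerate[1],
      attrs = .data$attrs[1],
      .groups = "drop"
    ) |>
    arrange(.data$chrom_a, .data$start_a, .data$chrom_b, .data$start_b)
}

#' Write intervals to a BED file
#'
#' Writes BED3/BED6+ depending on the columns present (`name`, `score`,
#' `strand`, then any extra columns in order).
#'
#' @param x Tibble with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @param extra_cols Character vector of additional columns to append after
#'   the BED6 fields.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, extra_cols = character()) {
  if (nrow(x) > 0) check_intervals(x, what = "BED record")
  cols <- list(x$chrom, format(x$start, trim = TRUE, scientific = FALSE),
               format(x$end, trim = TRUE, scientific = FALSE))
  for (c6 in c("name", "score", "strand")) {
    if (c6 %in% names(x)) cols <- c(cols, list(as.character(x[[c6]])))
  }
  for (ec in extra_cols) cols <- c(cols, list(as.character(x[[ec]])))
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write loop anchor pairs to a BEDPE file
#'
#' @param loops Tibble with `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b`; any columns named in `extra_cols` are appended.
#' @param path Output path.
#' @param extra_cols Additional columns appended after the six coordinates.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path, extra_cols = character()) {
  fmt <- function(v) format(v, trim = TRUE, scientific = FALSE)
  cols <- list(
    loops$chrom_a, fmt(loops$start_a), fmt(loops$end_a),
    loops$chrom_b, fmt(loops$start_b), fmt(loops$end_b)
  )
  for (ec in extra_cols) cols <- c(cols, list(as.character(loops[[ec]])))
  lines <- do.call(paste, c(cols, sep = "\t"))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' @param path FASTQ path (uncompressed or gzipped).
#' @return Tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  tibble(
    read_id = names(x),
    sequence = unname(as.character(x)),
    quality = unname(as.character(S4Vectors::mcols(x)$qualities))
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (quality string
#'   the same length as the sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) > 0 &&
    any(nchar(reads$sequence) != nchar(reads$quality))) {
    abort("sequence and quality strings must have equal length")
  }
  if (nrow(reads) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality)
  )
  invisible(path)
}
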