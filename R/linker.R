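# Bridge-linker splitting of chimeric Hi-C reads.
#
# In bridge-linker Hi-C protocols a short adapter is ligated between the two
# proximity-ligated genomic fragments, so a read spanning the junction is
# chimeric and must be cut at the linker before alignment. The search is a
# fixed-width (Hamming) scan - linkers are short and ligation errors are
# substitution-dominated, so indels are not modelled.

#' Configure the bridge-linker search
#'
#' The linker sequence is protocol-specific and therefore mandatory: there is
#' no default.
#'
#' @param linker_seq Linker DNA sequence (alphabet A/C/G/T/N).
#' @param max_mismatches Maximum Hamming mismatches tolerated; default 1.
#' @param min_fragment_len Shortest genomic fragment ever emitted, in bp;
#'   default 20 (fragments below the usual alignment-length floor are
#'   useless downstream).
#' @param search_both_strands Also search the reverse complement of the
#'   linker; default `TRUE` (the linker ligates in either orientation).
#' @return A `linker_config` list.
#' @export
linker_config <- function(linker_seq, max_mismatches = 1L,
                          min_fragment_len = 20L,
                          search_both_strands = TRUE) {
  if (missing(linker_seq) || !is.character(linker_seq) ||
    length(linker_seq) != 1 || !nzchar(linker_seq)) {
    abort("linker_seq is mandatory and must be a non-empty DNA string")
  }
  linker_seq <- toupper(linker_seq)
  if (grepl("[^ACGTN]", linker_seq)) {
    abort("linker_seq may only contain A, C, G, T, N")
  }
  if (max_mismatches < 0) abort("max_mismatches must be >= 0")
  if (min_fragment_len < 1) abort("min_fragment_len must be >= 1")
  structure(
    list(
      linker_seq = linker_seq,
      max_mismatches = as.integer(max_mismatches),
      min_fragment_len = as.integer(min_fragment_len),
      search_both_strands = isTRUE(search_both_strands)
    ),
    class = "linker_config"
  )
}

#' Find linker occurrences in a read
#'
#' Scans one read for the linker (and, optionally, its reverse complement)
#' allowing up to `max_mismatches` substitutions. A linker longer than the
#' read yields no hits.
#'
#' @param read_seq Read sequence (character scalar).
#' @param cfg A [linker_config()].
#' @return Tibble with `offset` (0-based position of the linker start),
#'   `strand` (`"+"` forward, `"-"` reverse complement) and `mismatches`,
#'   sorted by offset.
#' @export
find_linker <- function(read_seq, cfg) {
  stopifnot(inherits(cfg, "linker_config"))
  if (!is.character(read_seq) || length(read_seq) != 1 || nchar(read_seq) < 1) {
    abort("read_seq must be a single non-empty string")
  }
  if (nchar(cfg$linker_seq) > nchar(read_seq)) {
    return(tibble(offset = integer(), strand = character(), mismatches = integer()))
  }
  subject <- Biostrings::DNAString(read_seq)
  scan <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subject,
      max.mismatch = cfg$max_mismatches, fixed = TRUE
    )
    if (length(m) == 0) {
      return(NULL)
    }
    tibble(
      offset = Biostrings::start(m) - 1L,
      strand = strand,
      mismatches = unname(vapply(
        as.character(m),
        function(s) hamming_distance(s, as.character(pattern)),
        integer(1)
      ))
    )
  }
  hits <- scan(cfg$linker_seq, "+")
  if (cfg$search_both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cfg$linker_seq)))
    if (rc != cfg$linker_seq) hits <- bind_rows(hits, scan(rc, "-"))
  }
  if (is.null(hits) || nrow(hits) == 0) {
    return(tibble(offset = integer(), strand = character(), mismatches = integer()))
  }
  arrange(hits, .data$offset, .data$strand)
}

hamming_distance <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Split one read at the bridge linker
#'
#' With a single linker hit the read is cut into its left and right genomic
#' flanks, qualities sliced in lockstep; flanks shorter than
#' `min_fragment_len` are dropped (status stays `"split"` unless both drop,
#' which gives `"too_short"`). With two or more hits only the outermost
#' flanks are kept (internal fragments between linkers are ligation
#' artifacts) and the status is `"multi_linker"`. With no hit the read passes
#' through untouched as `"no_linker"`.
#'
#' @param sequence,quality Read sequence and quality strings (equal length).
#' @param cfg A [linker_config()].
#' @param read_id Read name used to derive fragment names (`_1`, `_2`).
#' @return List with `status` (`"split"`, `"no_linker"`, `"too_short"`,
#'   `"multi_linker"`) and `fragments`, a tibble of `read_id`, `sequence`,
#'   `quality`.
#' @export
split_read <- function(sequence, quality, cfg, read_id = "read") {
  stopifnot(inherits(cfg, "linker_config"))
  if (nchar(sequence) != nchar(quality)) {
    abort("sequence and quality strings must have equal length")
  }
  hits <- find_linker(sequence, cfg)
  if (nrow(hits) == 0) {
    return(list(
      status = "no_linker",
      fragments = tibble(read_id = read_id, sequence = sequence, quality = quality)
    ))
  }
  llen <- nchar(cfg$linker_seq)
  left_end <- hits$offset[1] # exclusive
  right_start <- hits$offset[nrow(hits)] + llen # inclusive, 0-based
  frag <- function(from, to, suffix) { # 0-based half-open
    if (to - from < cfg$min_fragment_len) {
      return(NULL)
    }
    tibble(
      read_id = paste0(read_id, suffix),
      sequence = substr(sequence, from + 1, to),
      quality = substr(quality, from + 1, to)
    )
  }
  fragments <- bind_rows(
    frag(0L, left_end, "_1"),
    frag(right_start, nchar(sequence), "_2")
  )
  status <- if (nrow(hits) >= 2) {
    "multi_linker"
  } else if (nrow(fragments) == 0) {
    "too_short"
  } else {
    "split"
  }
  list(status = status, fragments = fragments)
}

#' Split a batch of single-end reads
#'
#' Applies [split_read()] to every read and streams the results into the same
#' output groups the splitter writes to disk: genomic fragments, untouched
#' linker-free reads, and per-read accounting.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (see
#'   [read_fastq()]).
#' @param cfg A [linker_config()].
#' @return A `linker_split` object: list with `fragments` (emitted genomic
#'   sub-reads), `no_linker` (reads passed through unchanged), `per_read`
#'   (read_id, status, n_hits, first junction offset) and `stats` (one row of
#'   status counts; statuses always sum to the input read count).
#' @export
split_reads <- function(reads, cfg) {
  results <- purrr::pmap(
    list(reads$sequence, reads$quality, reads$read_id),
    function(s, q, id) {
      r <- split_read(s, q, cfg, read_id = id)
      hits <- find_linker(s, cfg)
      list(
        status = r$status, fragments = r$fragments,
        n_hits = nrow(hits),
        junction_offset = if (nrow(hits) > 0) hits$offset[1] else NA_integer_
      )
    }
  )
  status <- vapply(results, `[[`, character(1), "status")
  per_read <- tibble(
    read_id = reads$read_id,
    status = status,
    n_hits = vapply(results, `[[`, integer(1), "n_hits"),
    junction_offset = vapply(results, `[[`, integer(1), "junction_offset")
  )
  fragments <- bind_rows(purrr::map(
    results[status != "no_linker"], `[[`, "fragments"
  ))
  if (nrow(fragments) == 0) {
    fragments <- tibble(read_id = character(), sequence = character(), quality = character())
  }
  stats <- tibble(
    n_input = nrow(reads),
    n_split = sum(status == "split"),
    n_no_linker = sum(status == "no_linker"),
    n_too_short = sum(status == "too_short"),
    n_multi_linker = sum(status == "multi_linker")
  )
  structure(
    list(
      fragments = fragments,
      no_linker = reads[status == "no_linker", , drop = FALSE],
      per_read = per_read, stats = stats
    ),
    class = "linker_split"
  )
}

#' @describeIn split_reads Per-read status table.
#' @param x A `linker_split` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.linker_split <- function(x, ...) x$per_read

#' @describeIn split_reads One-row status counts.
#' @exportS3Method generics::glance
glance.linker_split <- function(x, ...) x$stats

#' Split paired-end mates at the bridge linker
#'
#' In paired-end mode each mate is scanned independently and trimmed at its
#' first linker occurrence, keeping the 5' genomic flank (the sequence past
#' the linker belongs to the ligation partner and is discarded). Mates
#' without a linker pass through intact.
#'
#' @param reads1,reads2 Mate tibbles (`read_id`, `sequence`, `quality`); ids
#'   must match pairwise after stripping a trailing `/1` or `/2`.
#' @param cfg A [linker_config()].
#' @return Tibble with one row per pair: `read_id`, then per mate `sequence`,
#'   `quality` and `status` (`NA` sequence when the trimmed flank fell below
#'   `min_fragment_len`).
#' @export
split_pe <- function(reads1, reads2, cfg) {
  stopifnot(inherits(cfg, "linker_config"))
  strip <- function(id) sub("/[12]$", "", id)
  if (nrow(reads1) != nrow(reads2) ||
    !all(strip(reads1$read_id) == strip(reads2$read_id))) {
    abort("mate ids do not match between reads1 and reads2")
  }
  trim_mate <- function(sequence, quality) {
    if (nchar(sequence) != nchar(quality)) {
      abort("sequence and quality strings must have equal length")
    }
    hits <- find_linker(sequence, cfg)
    if (nrow(hits) == 0) {
      return(list(sequence = sequence, quality = quality, status = "no_linker"))
    }
    keep <- hits$offset[1]
    if (keep < cfg$min_fragment_len) {
      return(list(sequence = NA_character_, quality = NA_character_, status = "too_short"))
    }
    list(
      sequence = substr(sequence, 1, keep),
      quality = substr(quality, 1, keep),
      status = if (nrow(hits) >= 2) "multi_linker" else "split"
    )
  }
  m1 <- purrr::map2(reads1$sequence, reads1$quality, trim_mate)
  m2 <- purrr::map2(reads2$sequence, reads2$quality, trim_mate)
  pick <- function(m, f) vapply(m, `[[`, character(1), f)
  tibble(
    read_id = strip(reads1$read_id),
    sequence_1 = pick(m1, "sequence"), quality_1 = pick(m1, "quality"),
    status_1 = pick(m1, "status"),
    sequence_2 = pick(m2, "sequence"), quality_2 = pick(m2, "quality"),
    status_2 = pick(m2, "status")
  )
}
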