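# Peak filtering and promoter/enhancer classification.
#
# Operational definitions, on significance-filtered peaks:
#   promoter = accessible region carrying all three signals
#              (ATAC-seq + H3K4me3 + H3K27ac)
#   enhancer = accessible region carrying ATAC-seq + H3K27ac but no H3K4me3
# Overlap means >= 1 shared bp under the half-open convention; strand is
# ignored (peaks are unstranded).

#' Filter peaks on -log10(P)
#'
#' Keeps peaks whose `neglog10_p` is strictly greater than the threshold.
#' A peak at exactly the threshold is dropped.
#'
#' @param peaks Peak tibble (see [read_narrowpeak()]).
#' @param min_neglog10_p Significance threshold on the -log10(P) scale;
#'   default 5, i.e. P < 1e-5.
#' @return The surviving peaks, input order preserved.
#' @export
filter_peaks <- function(peaks, min_neglog10_p = 5) {
  if (!is.numeric(min_neglog10_p) || length(min_neglog10_p) != 1 ||
    is.na(min_neglog10_p) || min_neglog10_p < 0) {
    abort("min_neglog10_p must be a single non-negative number")
  }
  peaks[peaks$neglog10_p > min_neglog10_p, , drop = FALSE]
}

#' Classify accessible regions into promoters and enhancers
#'
#' Integrates three significance-filtered peak tracks. In `"atac-anchored"`
#' mode (default) each ATAC peak yields at most one element whose interval is
#' the ATAC peak itself: a promoter if it overlaps at least one H3K4me3 peak
#' and at least one H3K27ac peak, an enhancer if it overlaps at least one
#' H3K27ac peak and no H3K4me3 peak, otherwise nothing. In `"intersection"`
#' mode the element interval is instead the maximal region simultaneously
#' covered by all required tracks (the stricter reading of "overlapping
#' signals").
#'
#' @param atac,h3k4me3,h3k27ac Peak tibbles, each already passed through
#'   [filter_peaks()].
#' @param mode `"atac-anchored"` or `"intersection"`.
#' @return Tibble of elements with columns `chrom`, `start`, `end`,
#'   `element_id`, `element_class` (`"promoter"`/`"enhancer"`), `evidence`
#'   (comma-joined subset of `ATAC,H3K27ac,H3K4me3`), `source_peaks`
#'   (comma-joined contributing peak names) and `mode`, sorted by
#'   (chrom, start). Output does not depend on input peak order.
#' @examples
#' atac <- tibble::tibble(chrom = "chr1", start = 100L, end = 300L,
#'                        name = "atac_1", neglog10_p = 8)
#' k4 <- tibble::tibble(chrom = "chr1", start = 150L, end = 250L,
#'                      name = "k4_1", neglog10_p = 8)
#' k27 <- tibble::tibble(chrom = "chr1", start = 120L, end = 260L,
#'                       name = "k27_1", neglog10_p = 8)
#' classify_elements(atac, k4, k27)
#' @export
classify_elements <- function(atac, h3k4me3, h3k27ac,
                              mode = c("atac-anchored", "intersection")) {
  mode <- match.arg(mode)
  for (df in list(atac, h3k4me3, h3k27ac)) {
    if (nrow(df) > 0) check_intervals(df, what = "peak")
  }
  atac <- arrange(atac, .data$chrom, .data$start, .data$end)
  h3k4me3 <- arrange(h3k4me3, .data$chrom, .data$start, .data$end)
  h3k27ac <- arrange(h3k27ac, .data$chrom, .data$start, .data$end)
  if (mode == "atac-anchored") {
    classify_atac_anchored(atac, h3k4me3, h3k27ac)
  } else {
    classify_intersection(atac, h3k4me3, h3k27ac)
  }
}

element_tibble <- function(chrom, start, end, class, evidence, source_peaks, mode) {
  out <- tibble(
    chrom = chrom, start = start, end = end,
    element_class = class, evidence = evidence,
    source_peaks = source_peaks, mode = mode
  ) |>
    arrange(.data$chrom, .data$start, .data$end)
  out$element_id <- sprintf(
    "%s_%03d", out$element_class,
    stats::ave(seq_len(nrow(out)), out$element_class, FUN = seq_along)
  )
  select(
    out, "chrom", "start", "end", "element_id", "element_class",
    "evidence", "source_peaks", "mode"
  )
}

classify_atac_anchored <- function(atac, h3k4me3, h3k27ac) {
  n <- nrow(atac)
  hits_k4 <- overlap_join(atac, h3k4me3)
  hits_k27 <- overlap_join(atac, h3k27ac)
  has_k4 <- seq_len(n) %in% hits_k4$x_idx
  has_k27 <- seq_len(n) %in% hits_k27$x_idx
  class <- dplyr::case_when(
    has_k4 & has_k27 ~ "promoter",
    !has_k4 & has_k27 ~ "enhancer",
    TRUE ~ NA_character_
  )
  keep <- which(!is.na(class))
  src <- function(i) {
    marks <- c(
      h3k4me3$name[hits_k4$y_idx[hits_k4$x_idx == i]],
      h3k27ac$name[hits_k27$y_idx[hits_k27$x_idx == i]]
    )
    paste(c(atac$name[i], marks), collapse = ",")
  }
  element_tibble(
    chrom = atac$chrom[keep], start = atac$start[keep], end = atac$end[keep],
    class = class[keep],
    evidence = ifelse(class[keep] == "promoter",
      "ATAC,H3K27ac,H3K4me3", "ATAC,H3K27ac"
    ),
    source_peaks = vapply(keep, src, character(1)),
    mode = "atac-anchored"
  )
}

# maximal regions simultaneously covered by all required tracks: promoters
# from the triple intersection, enhancers from ATAC * H3K27ac minus any
# region touching H3K4me3
classify_intersection <- function(atac, h3k4me3, h3k27ac) {
  gr <- function(df) {
    if (nrow(df) == 0) {
      GenomicRanges::GRanges()
    } else {
      GenomicRanges::reduce(intervals_to_granges(df))
    }
  }
  g_atac <- gr(atac)
  g_k4 <- gr(h3k4me3)
  g_k27 <- gr(h3k27ac)
  prom <- GenomicRanges::intersect(GenomicRanges::intersect(g_atac, g_k4), g_k27)
  enh_all <- GenomicRanges::intersect(g_atac, g_k27)
  enh <- enh_all[!IRanges::overlapsAny(enh_all, g_k4)]
  to_df <- function(g, class, evidence) {
    if (length(g) == 0) {
      return(NULL)
    }
    tibble(
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1L,
      end = GenomicRanges::end(g),
      class = class, evidence = evidence
    )
  }
  parts <- bind_rows(
    to_df(prom, "promoter", "ATAC,H3K27ac,H3K4me3"),
    to_df(enh, "enhancer", "ATAC,H3K27ac")
  )
  if (is.null(parts) || nrow(parts) == 0) {
    return(element_tibble(
      character(), integer(), integer(), character(), character(),
      character(), character()
    ))
  }
  src <- vapply(seq_len(nrow(parts)), function(i) {
    iv <- parts[i, ]
    nm <- c(
      atac$name[interval_overlaps(atac$chrom, atac$start, atac$end, iv$chrom, iv$start, iv$end)],
      h3k4me3$name[interval_overlaps(h3k4me3$chrom, h3k4me3$start, h3k4me3$end, iv$chrom, iv$start, iv$end)],
      h3k27ac$name[interval_overlaps(h3k27ac$chrom, h3k27ac$start, h3k27ac$end, iv$chrom, iv$start, iv$end)]
    )
    paste(nm, collapse = ",")
  }, character(1))
  element_tibble(
    chrom = parts$chrom, start = parts$start, end = parts$end,
    class = parts$class, evidence = parts$evidence,
    source_peaks = src, mode = "intersection"
  )
}
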