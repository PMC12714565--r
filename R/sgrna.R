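# CRISPRi sgRNA selection from a CHOPCHOP-like candidate table.
#
# Selection rule: keep candidates with a perfect on-target match and an
# efficiency score strictly above 60, then rank ascending lexicographically
# on the off-target counts (MM0, MM1, MM2, MM3) - fewest perfect off-targets
# first, then 1-mismatch sites, and so on - breaking ties by higher
# efficiency and finally input order; take the top three.

#' Validate an sgRNA candidate table
#'
#' @param candidates Tibble with columns `guide_seq` (20 nt), `pam` (NGG),
#'   `strand`, `tss_offset`, `efficiency` (0-100), `mm0`-`mm3`,
#'   `on_target_mismatches`.
#' @return The validated tibble, invisibly coerced column types.
#' @export
validate_sgrna <- function(candidates) {
  candidates <- as_tibble(candidates)
  req <- c(
    "guide_seq", "pam", "tss_offset", "efficiency",
    "mm0", "mm1", "mm2", "mm3", "on_target_mismatches"
  )
  missing_cols <- setdiff(req, names(candidates))
  if (length(missing_cols) > 0) {
    abort(paste0("candidate table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(candidates) == 0) {
    return(candidates)
  }
  if (any(nchar(candidates$guide_seq) != 20L)) {
    abort("every guide_seq must be exactly 20 nt")
  }
  if (any(!grepl("^[ACGTN]GG$", toupper(candidates$pam)))) {
    abort("every PAM must match NGG")
  }
  if (any(candidates$efficiency < 0 | candidates$efficiency > 100)) {
    abort("efficiency must lie in [0, 100]")
  }
  mmcols <- c("mm0", "mm1", "mm2", "mm3")
  if (any(as.matrix(candidates[mmcols]) < 0)) {
    abort("MM0-MM3 counts must be non-negative")
  }
  candidates
}

#' Select the top sgRNAs
#'
#' Applies the two-step rule: (1) keep candidates with
#' `on_target_mismatches == 0` and `efficiency > min_efficiency` (strict; a
#' score of exactly 60 is excluded under the default); (2) rank survivors
#' lexicographically ascending on `(mm0, mm1, mm2, mm3)`, ties broken by
#' descending efficiency then by input order, and return the first `n`.
#'
#' @param candidates Candidate tibble (see [validate_sgrna()]).
#' @param n Number of guides to return; default 3.
#' @param min_efficiency Strict lower bound on the efficiency score;
#'   default 60.
#' @return The selected candidates with a `rank` column, at most `n` rows.
#' @export
select_top_sgrnas <- function(candidates, n = 3L, min_efficiency = 60) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("n must be a positive integer")
  }
  candidates <- validate_sgrna(candidates)
  survivors <- candidates |>
    mutate(.input_order = row_number()) |>
    filter(.data$on_target_mismatches == 0, .data$efficiency > min_efficiency)
  ranked <- survivors |>
    arrange(
      .data$mm0, .data$mm1, .data$mm2, .data$mm3,
      dplyr::desc(.data$efficiency), .data$.input_order
    ) |>
    mutate(rank = row_number()) |>
    select(-".input_order")
  head(ranked, n)
}

#' Test whether a guide lies in the CRISPRi targeting window
#'
#' The effective CRISPRi window spans -50 bp to +400 bp around the
#' transcription start site; both boundaries are inclusive.
#'
#' @param tss_offset Signed guide-start position relative to the TSS
#'   (strand-aware bp); vectorized.
#' @param window_start,window_end Window bounds in bp; defaults -50 and +400.
#' @return Logical vector.
#' @export
in_tss_window <- function(tss_offset, window_start = -50, window_end = 400) {
  if (window_start > window_end) {
    abort("window_start must not exceed window_end")
  }
  tss_offset >= window_start & tss_offset <= window_end
}

#' Annotate guide sites with chromatin evidence
#'
#' Reports, for each guide target site, which of the supplied peak tracks
#' (e.g. ATAC, H3K27ac, H3K4me3) overlap it by at least 1 bp - the marks used
#' to confirm that a guide targets accessible, active chromatin.
#'
#' @param sites Tibble of guide target intervals: `chrom`, `start`, `end`.
#' @param tracks Named list of peak tibbles, e.g.
#'   `list(ATAC = ..., H3K27ac = ..., H3K4me3 = ...)`.
#' @return `sites` with a logical column per track and `evidence`
#'   (comma-joined names of the overlapping tracks).
#' @export
annotate_chromatin <- function(sites, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    abort("tracks must be a named list of peak tibbles")
  }
  sites <- as_tibble(sites)
  for (nm in names(tracks)) {
    hits <- overlap_join(sites, tracks[[nm]])
    sites[[nm]] <- seq_len(nrow(sites)) %in% hits$x_idx
  }
  flags <- as.matrix(sites[names(tracks)])
  sites$evidence <- apply(flags, 1, function(r) {
    paste(names(tracks)[r], collapse = ",")
  })
  sites
}
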