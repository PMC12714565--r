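# Independent brute-force oracles, deliberately naive: each re-derives the
# expected answer by enumeration rather than reusing package internals.

# per-base set intersection on 0-based half-open intervals
oracle_overlap <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  if (chrom_a != chrom_b) {
    return(FALSE)
  }
  a <- seq.int(start_a, end_a - 1L)
  b <- seq.int(start_b, end_b - 1L)
  length(intersect(a, b)) > 0
}

# positional Hamming scan for a pattern in a read (forward strand only)
oracle_hamming_hits <- function(read, pattern, max_mm) {
  n <- nchar(read)
  k <- nchar(pattern)
  if (k > n) {
    return(integer(0))
  }
  pat <- strsplit(pattern, "")[[1]]
  rd <- strsplit(read, "")[[1]]
  offs <- integer(0)
  for (off in 0:(n - k)) {
    if (sum(rd[(off + 1):(off + k)] != pat) <= max_mm) offs <- c(offs, off)
  }
  offs
}

# insertion sort of sgRNA candidates under the selection comparator:
# lexicographic ascending (mm0, mm1, mm2, mm3), then higher efficiency,
# then earlier input position
oracle_sgrna_order <- function(df) {
  before <- function(i, j) {
    for (col in c("mm0", "mm1", "mm2", "mm3")) {
      if (df[[col]][i] != df[[col]][j]) {
        return(df[[col]][i] < df[[col]][j])
      }
    }
    if (df$efficiency[i] != df$efficiency[j]) {
      return(df$efficiency[i] > df$efficiency[j])
    }
    i < j
  }
  ord <- seq_len(nrow(df))
  for (a in seq_along(ord)[-1]) {
    b <- a
    while (b > 1 && before(ord[b], ord[b - 1])) {
      tmp <- ord[b - 1]
      ord[b - 1] <- ord[b]
      ord[b] <- tmp
      b <- b - 1
    }
  }
  ord
}

# minimal valid peak tibble
make_peaks <- function(chrom, start, end, name = NULL, neglog10_p = 8) {
  n <- length(start)
  tibble::tibble(
    chrom = rep_len(chrom, n), start = as.integer(start), end = as.integer(end),
    name = name %||% sprintf("pk_%03d", seq_len(n)),
    score = rep(500L, n), strand = rep(".", n),
    signal_value = rep(1, n),
    neglog10_p = rep_len(neglog10_p, n), neglog10_q = rep(-1, n),
    summit_offset = rep(-1L, n)
  )
}

make_loop <- function(chrom_a, start_a, end_a, chrom_b, start_b, end_b) {
  tibble::tibble(
    chrom_a = chrom_a, start_a = start_a, end_a = end_a,
    chrom_b = chrom_b, start_b = start_b, end_b = end_b,
    multiplicity = 1L,
    inter_chromosomal = chrom_a != chrom_b,
    degenerate = FALSE, attrs = NA_character_
  )
}

random_candidates <- function(n) {
  tibble::tibble(
    guide_seq = vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    }, character(1)),
    pam = sample(c("AGG", "TGG", "CGG", "GGG"), n, replace = TRUE),
    strand = sample(c("+", "-"), n, replace = TRUE),
    tss_offset = sample(-100:450, n, replace = TRUE),
    efficiency = round(runif(n, 0, 100), 1),
    mm0 = sample(0:3, n, replace = TRUE),
    mm1 = sample(0:4, n, replace = TRUE),
    mm2 = sample(0:6, n, replace = TRUE),
    mm3 = sample(0:9, n, replace = TRUE),
    on_target_mismatches = sample(c(0L, 0L, 0L, 1L), n, replace = TRUE)
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
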