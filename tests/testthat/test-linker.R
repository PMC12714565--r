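LINKER <- "ACGCGATATCTTATCTGACT"

test_that("linker hits agree with a positional Hamming-scan oracle", {
  cfg <- linker_config(LINKER, max_mismatches = 1, search_both_strands = FALSE)
  read <- paste0(strrep("ACGT", 5), LINKER, strrep("TTTT", 5))
  hits <- find_linker(read, cfg)
  expect_equal(hits$offset, 20L)
  expect_equal(hits$mismatches, 0L)

  expect_equal(nrow(find_linker(strrep("ACGT", 20), cfg)), 0)
  # 1-substitution copy: found at max_mm 1, absent at 0
  mut <- sub("^A", "T", LINKER)
  read_mut <- paste0(strrep("CCCC", 8), mut, strrep("GGGG", 8))
  expect_equal(find_linker(read_mut, cfg)$mismatches, 1L)
  cfg0 <- linker_config(LINKER, max_mismatches = 0, search_both_strands = FALSE)
  expect_equal(nrow(find_linker(read_mut, cfg0)), 0)

  withr::local_seed(13)
  for (i in 1:25) {
    read <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    for (mm in 0:2) {
      cfg_i <- linker_config(LINKER, max_mismatches = mm, search_both_strands = FALSE)
      expect_equal(
        find_linker(read, cfg_i)$offset,
        oracle_hamming_hits(read, LINKER, mm)
      )
    }
  }
})

test_that("a linker longer than the read yields no hits, not an error", {
  cfg <- linker_config(strrep("ACGT", 30))
  expect_equal(nrow(find_linker("ACGTACGT", cfg)), 0)
})

test_that("reverse-complement occurrences are reported when enabled", {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(LINKER)))
  read <- paste0(strrep("AAAA", 8), rc, strrep("CCCC", 8))
  cfg_both <- linker_config(LINKER, max_mismatches = 0, search_both_strands = TRUE)
  cfg_fwd <- linker_config(LINKER, max_mismatches = 0, search_both_strands = FALSE)
  expect_equal(find_linker(read, cfg_both)$strand, "-")
  expect_equal(nrow(find_linker(read, cfg_fwd)), 0)
})

test_that("split_read reconstructs, drops short flanks, and routes linker-free reads", {
  cfg <- linker_config(LINKER, max_mismatches = 0)
  left <- strrep("ACG", 10)
  right <- strrep("TGA", 10)
  read <- paste0(left, LINKER, right)
  qual <- strrep("I", nchar(read))
  res <- split_read(read, qual, cfg, read_id = "r1")
  expect_equal(res$status, "split")
  expect_equal(res$fragments$sequence, c(left, right))
  expect_equal(nchar(res$fragments$quality), nchar(res$fragments$sequence))
  # reconstruction at 0 mismatches
  expect_equal(paste0(res$fragments$sequence[1], LINKER, res$fragments$sequence[2]), read)

  # 19-bp left flank dropped under the 20-bp floor; right 40-bp kept
  short <- paste0(strrep("A", 19), LINKER, strrep("C", 40))
  res2 <- split_read(short, strrep("I", nchar(short)), cfg)
  expect_equal(res2$status, "split")
  expect_equal(res2$fragments$sequence, strrep("C", 40))

  both_short <- paste0(strrep("A", 5), LINKER, strrep("C", 5))
  expect_equal(split_read(both_short, strrep("I", nchar(both_short)), cfg)$status, "too_short")

  plain <- strrep("ACGT", 15)
  res3 <- split_read(plain, strrep("I", 60), cfg)
  expect_equal(res3$status, "no_linker")
  expect_equal(res3$fragments$sequence, plain) # passed through intact

  expect_error(split_read("ACGT", "II", cfg), "equal length")
})

test_that("multiple linkers keep only the outermost flanks", {
  cfg <- linker_config(LINKER, max_mismatches = 0)
  left <- strrep("ACG", 10)
  mid <- strrep("GTA", 10)
  right <- strrep("TGA", 10)
  read <- paste0(left, LINKER, mid, LINKER, right)
  res <- split_read(read, strrep("I", nchar(read)), cfg)
  expect_equal(res$status, "multi_linker")
  expect_equal(res$fragments$sequence, c(left, right)) # internal fragment discarded
})

test_that("batch splitting conserves reads and never emits short fragments", {
  withr::local_seed(29)
  cfg <- linker_config(LINKER, max_mismatches = 0)
  sim <- generate_chimeric_reads(sim_config(seed = 4, n_chimeric_reads = 120, flank_len_bp = c(15L, 60L)))
  # mix in linker-free reads
  plain <- tibble::tibble(
    read_id = sprintf("plain_%02d", 1:30),
    sequence = vapply(1:30, function(i) {
      paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE), collapse = "")
    }, character(1)),
    quality = strrep("I", 80)
  )
  plain <- plain[!grepl(LINKER, plain$sequence, fixed = TRUE), ]
  reads <- dplyr::bind_rows(sim$reads, plain)
  res <- split_reads(reads, cfg)
  st <- glance(res)
  expect_equal(
    st$n_split + st$n_no_linker + st$n_too_short + st$n_multi_linker,
    nrow(reads)
  )
  expect_true(all(nchar(res$fragments$sequence) >= cfg$min_fragment_len))
  expect_equal(nrow(res$no_linker), nrow(plain))
  # junction offsets match the planted truth
  per <- tidy(res)
  m <- match(sim$truth$read_id, per$read_id)
  expect_equal(per$junction_offset[m], sim$truth$junction_offset)
})

test_that("paired-end mates are trimmed independently and keep their pairing", {
  cfg <- linker_config(LINKER, max_mismatches = 0)
  left <- strrep("ACGTT", 8) # 40 bp
  r1 <- tibble::tibble(
    read_id = c("p1/1", "p2/1"),
    sequence = c(paste0(left, LINKER, strrep("G", 30)), strrep("ACGT", 20)),
    quality = c(strrep("I", 40 + 20 + 30), strrep("I", 80))
  )
  r2 <- tibble::tibble(
    read_id = c("p1/2", "p2/2"),
    sequence = c(strrep("TGCA", 20), strrep("GGCC", 20)),
    quality = c(strrep("I", 80), strrep("I", 80))
  )
  res <- split_pe(r1, r2, cfg)
  expect_equal(res$read_id, c("p1", "p2"))
  expect_equal(res$sequence_1[1], left) # trimmed at the linker
  expect_equal(res$status_1, c("split", "no_linker"))
  expect_equal(res$sequence_2[1], r2$sequence[1]) # mate untouched
  expect_equal(res$status_2, c("no_linker", "no_linker"))
  expect_error(split_pe(r1, r2[2:1, ], cfg), "mate ids")
})

test_that("linker configuration rejects invalid settings", {
  expect_error(linker_config(), "mandatory")
  expect_error(linker_config("ACGU"), "A, C, G, T, N")
  expect_error(linker_config("ACGT", min_fragment_len = 0), ">= 1")
})
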