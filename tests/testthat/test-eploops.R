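fixture_elements <- function() {
  atac <- make_peaks("chr3", c(1000, 41000, 81000), c(2000, 42000, 82000),
    name = c("aP", "aE", "aP2")
  )
  k4 <- make_peaks("chr3", c(1100, 81100), c(1900, 81900), name = c("k4P", "k4P2"))
  k27 <- make_peaks("chr3", c(1050, 41050, 81050), c(1950, 41950, 81950),
    name = c("k27P", "k27E", "k27P2")
  )
  classify_elements(atac, k4, k27)
}

test_that("loop categories follow the EP > PP > EE > PN/EN > NN precedence", {
  el <- fixture_elements() # promoters at ~1k-2k and ~81k-82k, enhancer ~41k-42k
  loops <- dplyr::bind_rows(
    make_loop("chr3", 500, 2500, "chr3", 40500, 42500), # P-E -> EP
    make_loop("chr3", 500, 2500, "chr3", 80500, 82500), # P-P
    make_loop("chr3", 40500, 42500, "chr3", 200000, 205000), # E-N
    make_loop("chr3", 200000, 205000, "chr3", 300000, 305000) # N-N
  )
  ann <- annotate_loops(loops, el)
  got <- ann[order(ann$start_a, ann$start_b), ]
  expect_equal(as.character(got$category), c("EP", "PP", "EN", "NN"))
  ep <- got[got$category == "EP", ]
  expect_match(ep$promoters_a, "promoter")
  expect_match(ep$enhancers_b, "enhancer")
})

test_that("distance is midpoint-to-midpoint and unset across chromosomes", {
  el <- fixture_elements()
  ann <- annotate_loops(make_loop("chr3", 1000, 6000, "chr3", 41000, 46000), el)
  expect_equal(ann$distance_bp, 40000)
  inter <- annotate_loops(make_loop("chr1", 1000, 6000, "chr2", 41000, 46000), el)
  expect_true(is.na(inter$distance_bp))
  expect_equal(as.character(inter$category), "NN")
})

test_that("swapping anchors changes neither category nor distance", {
  el <- fixture_elements()
  fwd <- make_loop("chr3", 500, 2500, "chr3", 40500, 42500)
  rev <- make_loop("chr3", 40500, 42500, "chr3", 500, 2500)
  a1 <- annotate_loops(fwd, el)
  a2 <- annotate_loops(rev, el)
  expect_equal(as.character(a1$category), as.character(a2$category))
  expect_equal(a1$distance_bp, a2$distance_bp)
})

test_that("an anchor carrying both classes is flagged but can still make an EP call", {
  # promoter and enhancer both under anchor a; enhancer under anchor b
  atac <- make_peaks("chr1", c(1000, 3000, 50000), c(2000, 4000, 51000),
    name = c("aP", "aE", "aE2")
  )
  k4 <- make_peaks("chr1", 1100, 1900, name = "k4")
  k27 <- make_peaks("chr1", c(1050, 3050, 50050), c(1950, 3950, 50950),
    name = c("k27a", "k27b", "k27c")
  )
  el <- classify_elements(atac, k4, k27)
  ann <- annotate_loops(make_loop("chr1", 500, 4500, "chr1", 49500, 51500), el)
  expect_equal(as.character(ann$category), "EP")
  expect_true(ann$ambiguous)
})

test_that("every loop gets exactly one category and counts are conserved", {
  withr::local_seed(17)
  cfg <- sim_config(seed = 207)
  tracks <- generate_tracks(cfg)
  loops <- generate_loops(cfg, tracks$truth)
  el <- classify_elements(
    filter_peaks(tracks$atac), filter_peaks(tracks$h3k4me3),
    filter_peaks(tracks$h3k27ac)
  )
  calls <- call_ep_loops(loops$loops, el)
  g <- glance(calls)
  expect_equal(
    g$n_EP + g$n_PP + g$n_EE + g$n_PN + g$n_EN + g$n_NN,
    nrow(loops$loops)
  )
  expect_equal(sort(tidy(calls)$loop_id), sort(loops$loops |> annotate_loops(el) |> dplyr::pull(loop_id)))
})

test_that("adding elements never demotes a loop below its previous category", {
  el <- fixture_elements()
  loops <- make_loop("chr3", 500, 2500, "chr3", 40500, 42500)
  prec <- c(NN = 0, EN = 1, PN = 1, EE = 2, PP = 3, EP = 4)
  before <- annotate_loops(loops, el[el$element_class == "promoter", ][1, ])
  after <- annotate_loops(loops, el)
  expect_gte(
    prec[[as.character(after$category)]],
    prec[[as.character(before$category)]]
  )
  expect_equal(as.character(after$category), "EP")
})

test_that("per-chromosome summary equals a brute-force tally and sums to the input", {
  withr::local_seed(41)
  chroms <- paste0("chr", 1:5)
  n <- 500
  ann <- tibble::tibble(
    chrom_a = sample(chroms, n, replace = TRUE),
    category = factor(sample(c("EP", "PP", "NN"), n,
      replace = TRUE, prob = c(0.3, 0.3, 0.4)
    ), levels = c("EP", "PP", "EE", "PN", "EN", "NN"))
  )
  smry <- summarize_by_chromosome(ann)
  expect_equal(sum(smry$n_total), n)
  for (ch in chroms) {
    n_ep <- 0
    n_non <- 0
    for (i in seq_len(n)) { # independent tally
      if (ann$chrom_a[i] == ch) {
        if (ann$category[i] == "EP") n_ep <- n_ep + 1 else n_non <- n_non + 1
      }
    }
    expect_equal(smry$n_ep[smry$chrom == ch], n_ep)
    expect_equal(smry$n_non_ep[smry$chrom == ch], n_non)
  }
})

test_that("empty loop sets annotate to empty outputs", {
  el <- fixture_elements()
  expect_equal(nrow(annotate_loops(make_loop(character(), double(), double(), character(), double(), double()), el)), 0)
  calls <- call_ep_loops(make_loop(character(), double(), double(), character(), double(), double()), el)
  expect_equal(nrow(calls$ep_loops), 0)
})
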