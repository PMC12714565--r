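# Seeded synthetic-data generator with planted ground truth.
#
# Emulates the statistical structure of the pipeline's real inputs at toy
# scale: peak tracks with controlled three-way overlap and -log10(P) values
# straddling the significance threshold, loop anchor pairs with planted
# category labels, chimeric bridge-linker reads, Ct tables with planted fold
# changes, and two-mask stain images with planted area ratios. Every emitted
# record traces to exactly one truth row. Each stage draws from its own
# sub-seed derived from the master seed, so adding or rerunning a stage never
# perturbs the draws of another.

#' Simulation configuration
#'
#' Defaults describe a toy study: 2 chromosomes x 1 Mb carrying 10 promoters,
#' 10 enhancers and 20 decoy sites, 35 loops across the five categories, 500
#' chimeric reads, knockdowns of 20/50/80 percent measured in 9 samples per
#' group with 0.1-cycle Ct noise, and a stain image whose positive region
#' covers a quarter of the yolk.
#'
#' @param seed Master seed; all stage sub-seeds derive from it.
#' @param n_chroms,chrom_length_bp Genome size.
#' @param n_promoters,n_enhancers,n_neutral_peaks Planted element and decoy
#'   counts. Decoys cycle through the classifier's failure modes:
#'   sub-threshold triple-mark sites (the first one sits exactly at
#'   -log10(P) = 5), ATAC-only, H3K4me3-only, H3K27ac-only and ATAC+H3K4me3
#'   sites.
#' @param peak_width_bp Min/max planted peak width.
#' @param neglog10_p_range Range of -log10(P) draws; must straddle 5 so both
#'   surviving and filtered peaks exist.
#' @param loop_counts Named counts for categories EP, EE, PP, PN, NN.
#' @param anchor_width_bp Loop anchor width (hiccups-like resolution).
#' @param boundary_jitter_bp Symmetric jitter applied to planted mark-peak
#'   and anchor boundaries; default 0 (noise-free regime).
#' @param linker_seq Bridge-linker sequence planted into chimeric reads.
#' @param n_chimeric_reads Number of simulated chimeric reads.
#' @param flank_len_bp Min/max genomic flank length around the linker.
#' @param knockdown_fractions Planted knockdown fractions in (0, 1); each
#'   yields a group with true fold change `1 - fraction`.
#' @param n_per_group Ct samples per group.
#' @param ct_noise_sd Gaussian noise SD on target Ct, in cycles.
#' @param image_shape Stain image height and width in pixels.
#' @param planted_area_fraction Fraction of yolk pixels made stain-positive.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 42L,
                       n_chroms = 2L, chrom_length_bp = 1000000L,
                       n_promoters = 10L, n_enhancers = 10L,
                       n_neutral_peaks = 20L,
                       peak_width_bp = c(200L, 800L),
                       neglog10_p_range = c(0.5, 10),
                       loop_counts = c(EP = 10L, EE = 5L, PP = 5L, PN = 5L, NN = 10L),
                       anchor_width_bp = 5000L,
                       boundary_jitter_bp = 0L,
                       linker_seq = "ACGCGATATCTTATCTGACT",
                       n_chimeric_reads = 500L,
                       flank_len_bp = c(30L, 60L),
                       knockdown_fractions = c(0.2, 0.5, 0.8),
                       n_per_group = 9L,
                       ct_noise_sd = 0.1,
                       image_shape = c(100L, 100L),
                       planted_area_fraction = 0.25) {
  cfg <- list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length_bp = as.integer(chrom_length_bp),
    n_promoters = as.integer(n_promoters),
    n_enhancers = as.integer(n_enhancers),
    n_neutral_peaks = as.integer(n_neutral_peaks),
    peak_width_bp = as.integer(peak_width_bp),
    neglog10_p_range = as.numeric(neglog10_p_range),
    loop_counts = loop_counts, anchor_width_bp = as.integer(anchor_width_bp),
    boundary_jitter_bp = as.integer(boundary_jitter_bp),
    linker_seq = toupper(linker_seq),
    n_chimeric_reads = as.integer(n_chimeric_reads),
    flank_len_bp = as.integer(flank_len_bp),
    knockdown_fractions = knockdown_fractions,
    n_per_group = as.integer(n_per_group),
    ct_noise_sd = ct_noise_sd,
    image_shape = as.integer(image_shape),
    planted_area_fraction = planted_area_fraction
  )
  counts <- unlist(cfg[c("n_promoters", "n_enhancers", "n_neutral_peaks", "n_chimeric_reads")])
  if (any(counts < 0)) abort("all counts must be >= 0")
  if (!(cfg$neglog10_p_range[1] < 5 && cfg$neglog10_p_range[2] > 5)) {
    abort("neglog10_p_range must straddle the threshold 5")
  }
  if (any(!names(cfg$loop_counts) %in% c("EP", "EE", "PP", "PN", "EN", "NN"))) {
    abort("loop_counts names must be among EP, EE, PP, PN, EN, NN")
  }
  if (any(cfg$loop_counts < 0)) abort("loop_counts must be >= 0")
  if (any(cfg$knockdown_fractions <= 0 | cfg$knockdown_fractions >= 1)) {
    abort("knockdown_fractions must lie in (0, 1)")
  }
  if (cfg$planted_area_fraction < 0 || cfg$planted_area_fraction > 1) {
    abort("planted_area_fraction must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

decoy_kinds <- c(
  "decoy_subthreshold", "decoy_atac_only", "decoy_h3k4me3_only",
  "decoy_h3k27ac_only", "decoy_atac_h3k4me3"
)

# lay out non-colliding element slots: each element owns a slot 4 anchor
# widths wide and sits at its center, so a planted anchor centered on the
# element never leaks into a neighboring slot
sim_slots <- function(cfg, n_needed) {
  slot_w <- 4L * cfg$anchor_width_bp
  per_chrom <- cfg$chrom_length_bp %/% slot_w
  slots <- tidyr::expand_grid(
    chrom = paste0("chr", seq_len(cfg$n_chroms)),
    slot = seq_len(per_chrom)
  ) |>
    mutate(center = (.data$slot - 1L) * slot_w + slot_w %/% 2L)
  if (n_needed > nrow(slots)) {
    abort(sprintf(
      "cannot place %d sites without collision: only %d slots available",
      n_needed, nrow(slots)
    ))
  }
  slots
}

jitter_bp <- function(n, j) {
  if (j <= 0) rep(0L, n) else sample.int(2L * j + 1L, n, replace = TRUE) - j - 1L
}

#' Generate planted peak tracks
#'
#' Emits three narrowPeak-schema peak tibbles (ATAC, H3K4me3, H3K27ac) plus a
#' truth table. Every planted promoter carries significant (-log10 P > 5)
#' peaks in all three tracks; every enhancer carries ATAC + H3K27ac only;
#' decoys cover the classifier's failure modes, including sub-threshold
#' sites.
#'
#' @param cfg A [sim_config()].
#' @return List with peak tibbles `atac`, `h3k4me3`, `h3k27ac` and `truth`
#'   (`element_id`, `chrom`, `start`, `end`, `true_class`).
#' @export
generate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stage_seed(cfg$seed, "tracks"), {
    n_elem <- cfg$n_promoters + cfg$n_enhancers + cfg$n_neutral_peaks
    # reserve slots for loop null-anchors too, so generate_loops stays
    # collision-free with the same layout
    n_null <- null_anchor_count(cfg)
    slots <- sim_slots(cfg, n_elem + n_null)
    classes <- c(
      rep("promoter", cfg$n_promoters),
      rep("enhancer", cfg$n_enhancers),
      rep(decoy_kinds, length.out = cfg$n_neutral_peaks)
    )
    # round-robin each class across chromosomes (random slot within the
    # chromosome) so same-chromosome loop pairs of every category exist
    chroms <- paste0("chr", seq_len(cfg$n_chroms))
    target_chrom <- unlist(lapply(
      c(cfg$n_promoters, cfg$n_enhancers, cfg$n_neutral_peaks),
      function(n) chroms[((seq_len(n) - 1L) %% cfg$n_chroms) + 1L]
    ), use.names = FALSE)
    slots_by_chrom <- split(seq_len(nrow(slots)), slots$chrom)
    pick <- integer(n_elem)
    for (ch in chroms) {
      idx <- which(target_chrom == ch)
      avail <- slots_by_chrom[[ch]]
      if (length(idx) > length(avail)) {
        abort(sprintf(
          "cannot place %d sites on %s without collision: only %d slots",
          length(idx), ch, length(avail)
        ))
      }
      pick[idx] <- resample_noreplace(avail, length(idx))
    }
    assigned <- slots[pick, , drop = FALSE]
    widths <- resample(seq(cfg$peak_width_bp[1], cfg$peak_width_bp[2]), n_elem)
    truth <- tibble(
      element_id = sprintf("site_%03d", seq_len(n_elem)),
      chrom = assigned$chrom,
      start = as.integer(assigned$center - widths %/% 2L),
      end = as.integer(assigned$center - widths %/% 2L + widths),
      true_class = classes
    ) |> arrange(.data$chrom, .data$start)
    hi_p <- function(n) runif(n, 5 + 0.5, cfg$neglog10_p_range[2])
    lo_p <- function(n) {
      p <- runif(n, cfg$neglog10_p_range[1], 5)
      if (n > 0) p[1] <- 5.0 # exercise the strict > 5 boundary
      p
    }
    mark_peak <- function(el, track) {
      w <- el$end - el$start
      shift <- jitter_bp(1L, max(cfg$boundary_jitter_bp, w %/% 8L))
      tibble(
        chrom = el$chrom,
        start = as.integer(max(0L, el$start + shift)),
        end = as.integer(el$end + jitter_bp(1L, cfg$boundary_jitter_bp)),
        name = paste0(track, "_", el$element_id)
      )
    }
    rows <- list(atac = list(), h3k4me3 = list(), h3k27ac = list())
    sig <- list(atac = list(), h3k4me3 = list(), h3k27ac = list())
    for (i in seq_len(nrow(truth))) {
      el <- truth[i, ]
      tracks_sig <- switch(el$true_class,
        promoter = c(atac = TRUE, h3k4me3 = TRUE, h3k27ac = TRUE),
        enhancer = c(atac = TRUE, h3k27ac = TRUE),
        decoy_subthreshold = c(atac = FALSE, h3k4me3 = FALSE, h3k27ac = FALSE),
        decoy_atac_only = c(atac = TRUE),
        decoy_h3k4me3_only = c(h3k4me3 = TRUE),
        decoy_h3k27ac_only = c(h3k27ac = TRUE),
        decoy_atac_h3k4me3 = c(atac = TRUE, h3k4me3 = TRUE)
      )
      for (track in names(tracks_sig)) {
        rows[[track]] <- c(rows[[track]], list(mark_peak(el, track)))
        sig[[track]] <- c(sig[[track]], list(tracks_sig[[track]]))
      }
    }
    mk_track <- function(track) {
      if (length(rows[[track]]) == 0) {
        return(write_ready_peaks(tibble(
          chrom = character(), start = integer(), end = integer(),
          name = character(), p = double()
        )))
      }
      df <- bind_rows(rows[[track]])
      is_sig <- unlist(sig[[track]])
      p <- numeric(nrow(df))
      p[is_sig] <- hi_p(sum(is_sig))
      p[!is_sig] <- lo_p(sum(!is_sig))
      df$p <- p
      write_ready_peaks(arrange(df, .data$chrom, .data$start))
    }
    list(
      atac = mk_track("atac"),
      h3k4me3 = mk_track("h3k4me3"),
      h3k27ac = mk_track("h3k27ac"),
      truth = truth
    )
  })
}

write_ready_peaks <- function(df) {
  tibble(
    chrom = df$chrom, start = df$start, end = df$end, name = df$name,
    score = pmin(1000L, as.integer(round(df$p * 100))),
    strand = rep(".", nrow(df)),
    signal_value = round(df$p * 2, 3),
    neglog10_p = round(df$p, 4),
    neglog10_q = rep(-1, nrow(df)),
    summit_offset = as.integer((df$end - df$start) %/% 2L)
  )
}

null_anchor_count <- function(cfg) {
  lc <- cfg$loop_counts
  n <- 0L
  if ("NN" %in% names(lc)) n <- n + 2L * lc[["NN"]]
  if ("PN" %in% names(lc)) n <- n + lc[["PN"]]
  if ("EN" %in% names(lc)) n <- n + lc[["EN"]]
  as.integer(n)
}

#' Generate planted loops
#'
#' Plants loop anchor pairs per category by centering anchors on truth
#' elements of the required classes (or on element-free slots for null
#' anchors), always pairing anchors on the same chromosome.
#'
#' @param cfg A [sim_config()].
#' @param truth Element truth table from [generate_tracks()].
#' @return List with `loops` (canonical loop tibble, see [read_loops()]) and
#'   `truth` (`loop_id`, anchors, `true_category`).
#' @export
generate_loops <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stage_seed(cfg$seed, "loops"), {
    lc <- cfg$loop_counts
    half <- cfg$anchor_width_bp %/% 2L
    # element-free slots for null anchors: recompute layout and drop
    # element-occupied slots
    n_elem <- cfg$n_promoters + cfg$n_enhancers + cfg$n_neutral_peaks
    slots <- sim_slots(cfg, n_elem + null_anchor_count(cfg))
    occupied <- overlap_join(
      mutate(slots, start = .data$center - half, end = .data$center + half),
      truth
    )
    free <- slots[setdiff(seq_len(nrow(slots)), occupied$x_idx), , drop = FALSE]
    pools <- list(
      P = filter(truth, .data$true_class == "promoter"),
      E = filter(truth, .data$true_class == "enhancer")
    )
    free_by_chrom <- split(seq_len(nrow(free)), free$chrom)
    free_used <- integer(0)
    take_free <- function(chrom) {
      avail <- setdiff(free_by_chrom[[chrom]] %||% integer(0), free_used)
      if (length(avail) == 0) {
        abort("ran out of element-free slots for null anchors")
      }
      free_used <<- c(free_used, avail[1])
      avail[1]
    }
    anchor_on <- function(el) {
      mid <- (el$start + el$end) %/% 2L
      j <- jitter_bp(2L, cfg$boundary_jitter_bp)
      tibble(
        chrom = el$chrom,
        start = as.integer(max(0L, mid - half + j[1])),
        end = as.integer(mid + half + j[2])
      )
    }
    pick_nth <- function(pool, chrom, idx) {
      cand <- pool[pool$chrom == chrom, , drop = FALSE]
      if (nrow(cand) == 0) {
        abort(paste0("no element of required class on ", chrom))
      }
      cand[(idx %% nrow(cand)) + 1L, , drop = FALSE]
    }
    out <- list()
    truth_rows <- list()
    counters <- new.env()
    seen <- character(0)
    li <- 0L
    for (cat in names(lc)) {
      for (r in seq_len(lc[[cat]])) {
        li <- li + 1L
        chrom <- paste0("chr", ((li - 1L) %% cfg$n_chroms) + 1L)
        need <- switch(cat,
          EP = c("P", "E"), PP = c("P", "P"), EE = c("E", "E"),
          PN = c("P", "N"), EN = c("E", "N"), NN = c("N", "N")
        )
        base_idx <- vapply(1:2, function(k) {
          if (need[k] == "N") {
            return(0L)
          }
          key <- paste(cat, k, need[k], chrom, sep = "_")
          cnt <- get0(key, envir = counters, ifnotfound = 0L)
          assign(key, cnt + 1L, envir = counters)
          # same-class pairs (PP, EE) stride by 2 so the two anchors of one
          # loop land on distinct elements
          if (need[1] == need[2] && need[1] != "N") cnt * 2L + (k - 1L) else cnt
        }, integer(1))
        # pair keys must be unique: anchors are deterministic per element, so
        # shift the second element until the pair is new (small pools can
        # otherwise replay a pair and collapse on dedup)
        attempt <- 0L
        repeat {
          anchors <- purrr::map(1:2, function(k) {
            if (need[k] == "N") {
              s <- free[take_free(chrom), ]
              tibble(
                chrom = s$chrom,
                start = as.integer(s$center - half),
                end = as.integer(s$center + half)
              )
            } else {
              idx <- base_idx[k] + if (k == 2L) attempt else 0L
              anchor_on(pick_nth(pools[[need[k]]], chrom, idx))
            }
          })
          pair_key <- paste(
            anchors[[1]]$chrom, anchors[[1]]$start,
            anchors[[2]]$chrom, anchors[[2]]$start,
            sep = ":"
          )
          if (!pair_key %in% seen) break
          attempt <- attempt + 1L
          if (attempt > 50L) {
            abort(sprintf(
              "cannot place a unique %s loop on %s: element supply exhausted",
              cat, chrom
            ))
          }
        }
        seen <- c(seen, pair_key)
        out[[li]] <- tibble(
          chrom_a = anchors[[1]]$chrom, start_a = anchors[[1]]$start,
          end_a = anchors[[1]]$end,
          chrom_b = anchors[[2]]$chrom, start_b = anchors[[2]]$start,
          end_b = anchors[[2]]$end
        )
        truth_rows[[li]] <- mutate(out[[li]],
          loop_id = sprintf("planted_%04d", li), true_category = cat
        )
      }
    }
    if (li == 0L) {
      return(list(loops = empty_loops(), truth = tibble(
        loop_id = character(), chrom_a = character(), start_a = double(),
        end_a = double(), chrom_b = character(), start_b = double(),
        end_b = double(), true_category = character()
      )))
    }
    loops <- canonicalize_loops(mutate(bind_rows(out), attrs = NA_character_))
    truth_tb <- bind_rows(truth_rows) |>
      canonicalize_truth() |>
      select(
        "loop_id", "chrom_a", "start_a", "end_a",
        "chrom_b", "start_b", "end_b", "true_category"
      )
    list(loops = loops, truth = truth_tb)
  })
}

# order truth anchors the same way canonicalize_loops orders loop anchors
canonicalize_truth <- function(truth) {
  swap <- (truth$chrom_a > truth$chrom_b) |
    (truth$chrom_a == truth$chrom_b & truth$start_a > truth$start_b)
  for (p in list(c("chrom_a", "chrom_b"), c("start_a", "start_b"), c("end_a", "end_b"))) {
    tmp <- truth[[p[1]]]
    truth[[p[1]]][swap] <- truth[[p[2]]][swap]
    truth[[p[2]]][swap] <- tmp[swap]
  }
  truth
}

#' Generate chimeric bridge-linker reads
#'
#' Each read is `left flank + linker + right flank` with random ACGT flanks
#' (re-drawn in the rare event a flank contains the linker by chance) and the
#' junction offset recorded in the truth table.
#'
#' @param cfg A [sim_config()].
#' @return List with `reads` (tibble `read_id`, `sequence`, `quality`) and
#'   `truth` (`read_id`, `junction_offset` = left flank length, `left_len`,
#'   `right_len`).
#' @export
generate_chimeric_reads <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stage_seed(cfg$seed, "reads"), {
    n <- cfg$n_chimeric_reads
    rand_flank <- function(len) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
        if (!grepl(cfg$linker_seq, s, fixed = TRUE)) {
          return(s)
        }
      }
    }
    left_len <- resample(seq(cfg$flank_len_bp[1], cfg$flank_len_bp[2]), n)
    right_len <- resample(seq(cfg$flank_len_bp[1], cfg$flank_len_bp[2]), n)
    seqs <- vapply(seq_len(n), function(i) {
      paste0(rand_flank(left_len[i]), cfg$linker_seq, rand_flank(right_len[i]))
    }, character(1))
    reads <- tibble(
      read_id = sprintf("chimera_%04d", seq_len(n)),
      sequence = seqs,
      quality = strrep("I", nchar(seqs))
    )
    truth <- tibble(
      read_id = reads$read_id,
      junction_offset = as.integer(left_len),
      left_len = as.integer(left_len),
      right_len = as.integer(right_len)
    )
    list(reads = reads, truth = truth)
  })
}

#' Generate a qPCR Ct table with planted fold changes
#'
#' Builds a calibrator group (`sgCtrl`, true fold 1) plus one group per
#' knockdown fraction with true fold `1 - fraction`, planting the fold
#' through the target Ct (`ddCt = -log2(fold)`) with Gaussian noise.
#'
#' @param cfg A [sim_config()].
#' @return List with `ct` (tibble `sample_id`, `group`, `target_ct`,
#'   `reference_ct`) and `truth` (`group`, `true_fold`).
#' @export
generate_ct_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(stage_seed(cfg$seed, "ct"), {
    folds <- c(1, 1 - cfg$knockdown_fractions)
    groups <- c("sgCtrl", sprintf("kd%02d", round(100 * cfg$knockdown_fractions)))
    base_ref <- 15
    base_dct <- 5
    ct <- purrr::map2(groups, folds, function(g, f) {
      tibble(
        sample_id = sprintf("%s_s%02d", g, seq_len(cfg$n_per_group)),
        group = g,
        target_ct = base_ref + base_dct - log2(f) +
          rnorm(cfg$n_per_group, 0, cfg$ct_noise_sd),
        reference_ct = base_ref
      )
    }) |> bind_rows()
    list(ct = ct, truth = tibble(group = groups, true_fold = folds))
  })
}

#' Generate a stain image with a planted area ratio
#'
#' The yolk is a centered rectangle of half the image height and width; the
#' stain-positive region fills exactly
#' `round(planted_area_fraction * yolk_pixels)` yolk pixels (full rows plus a
#' partial row) with an in-bounds stain color; all other pixels are
#' out-of-bounds colors. The matching threshold preset is returned alongside.
#'
#' @param cfg A [sim_config()].
#' @return List with `image` (0-255 RGB array), `yolk_mask` (logical matrix),
#'   `bounds` (threshold preset isolating the stain color) and `truth`
#'   (`true_positive_pixels`, `true_yolk_pixels`, `planted_fraction`).
#' @export
generate_stain_image <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  h <- cfg$image_shape[1]
  w <- cfg$image_shape[2]
  yolk_h <- h %/% 2L
  yolk_w <- w %/% 2L
  r0 <- (h - yolk_h) %/% 2L
  c0 <- (w - yolk_w) %/% 2L
  yolk_mask <- matrix(FALSE, h, w)
  yolk_mask[r0 + seq_len(yolk_h), c0 + seq_len(yolk_w)] <- TRUE
  yolk_px <- yolk_h * yolk_w
  n_pos <- as.integer(round(cfg$planted_area_fraction * yolk_px))
  pos_mask <- matrix(FALSE, h, w)
  if (n_pos > 0) {
    full_rows <- n_pos %/% yolk_w
    rem <- n_pos %% yolk_w
    if (full_rows > 0) {
      pos_mask[r0 + seq_len(full_rows), c0 + seq_len(yolk_w)] <- TRUE
    }
    if (rem > 0) pos_mask[r0 + full_rows + 1L, c0 + seq_len(rem)] <- TRUE
  }
  stain <- c(150, 90, 60) # in-bounds brown
  yolk_bg <- c(220, 190, 140) # inside yolk, G out of bounds
  bg <- c(240, 240, 240) # outside yolk, out of bounds
  image <- array(0, dim = c(h, w, 3))
  for (i in 1:3) {
    plane <- matrix(bg[i], h, w)
    plane[yolk_mask] <- yolk_bg[i]
    plane[pos_mask] <- stain[i]
    image[, , i] <- plane
  }
  bounds <- list(R = c(100, 200), G = c(50, 150), B = c(0, 105))
  list(
    image = image, yolk_mask = yolk_mask, bounds = bounds,
    truth = tibble(
      true_positive_pixels = n_pos, true_yolk_pixels = yolk_px,
      planted_fraction = cfg$planted_area_fraction
    )
  )
}

#' Generate every pipeline input, optionally writing files
#'
#' Runs all generator stages from one configuration. When `dir` is given, the
#' standard input files are written there (`atac.narrowPeak`,
#' `h3k4me3.narrowPeak`, `h3k27ac.narrowPeak`, `loops.bedpe`, `reads.fastq`,
#' `ct.tsv`, `stain.png`, `yolk_mask.png` and `truth/*.tsv`); identical
#' (seed, config) pairs produce byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return List with components `tracks`, `loops`, `reads`, `ct`, `stain`
#'   (each a stage result incl. its truth table) and `dir`.
#' @export
simulate_inputs <- function(cfg, dir = NULL) {
  tracks <- generate_tracks(cfg)
  loops <- generate_loops(cfg, tracks$truth)
  reads <- generate_chimeric_reads(cfg)
  ct <- generate_ct_table(cfg)
  stain <- generate_stain_image(cfg)
  if (!is.null(dir)) {
    dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
    write_narrowpeak(tracks$atac, file.path(dir, "atac.narrowPeak"))
    write_narrowpeak(tracks$h3k4me3, file.path(dir, "h3k4me3.narrowPeak"))
    write_narrowpeak(tracks$h3k27ac, file.path(dir, "h3k27ac.narrowPeak"))
    write_bedpe(loops$loops, file.path(dir, "loops.bedpe"))
    write_fastq(reads$reads, file.path(dir, "reads.fastq"))
    readr::write_tsv(ct$ct, file.path(dir, "ct.tsv"))
    write_rgb_image(stain$image, file.path(dir, "stain.png"))
    png::writePNG(stain$yolk_mask * 1, file.path(dir, "yolk_mask.png"))
    readr::write_tsv(tracks$truth, file.path(dir, "truth", "elements.tsv"))
    readr::write_tsv(loops$truth, file.path(dir, "truth", "loops.tsv"))
    readr::write_tsv(reads$truth, file.path(dir, "truth", "reads.tsv"))
    readr::write_tsv(ct$truth, file.path(dir, "truth", "folds.tsv"))
    readr::write_tsv(stain$truth, file.path(dir, "truth", "image.tsv"))
  }
  list(tracks = tracks, loops = loops, reads = reads, ct = ct, stain = stain, dir = dir)
}
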