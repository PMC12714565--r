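test_that("ddCt closed forms hold and the calibrator is centred at fold 1", {
  ct <- tibble::tibble(
    sample_id = sprintf("s%d", 1:6),
    group = rep(c("ctrl", "half", "quad"), each = 2),
    target_ct = c(20, 20, 21, 21, 18, 18), # ddCt 0, +1, -2
    reference_ct = 15
  )
  fit <- relative_expression(ct, "ctrl")
  tg <- tidy(fit)
  expect_equal(tg$mean_fold[tg$group == "ctrl"], 1)
  expect_equal(tg$mean_fold[tg$group == "half"], 0.5)
  expect_equal(tg$mean_fold[tg$group == "quad"], 4)
  # log2(fold) == -ddCt to machine precision, per sample
  expect_equal(log2(fit$samples$fold_change), -fit$samples$delta_delta_ct)
  expect_error(relative_expression(ct, "missing_group"), "calibrator")
  expect_error(
    relative_expression(dplyr::mutate(ct, target_ct = 50), "ctrl"),
    "0, 45"
  )
})

test_that("the calibrator geometric-mean fold is exactly 1 even under noise", {
  withr::local_seed(2)
  ct <- tibble::tibble(
    sample_id = sprintf("s%d", 1:12),
    group = rep(c("ctrl", "kd"), each = 6),
    target_ct = 20 + rnorm(12, 0, 0.3),
    reference_ct = 15 + rnorm(12, 0, 0.3)
  )
  fit <- relative_expression(ct, "ctrl")
  cal <- fit$samples$fold_change[fit$samples$group == "ctrl"]
  expect_equal(exp(mean(log(cal))), 1)
})

test_that("planted knockdown fractions are recovered from noisy Ct tables", {
  # noise-free tables recover folds exactly
  cfg0 <- sim_config(seed = 5, ct_noise_sd = 0)
  g0 <- generate_ct_table(cfg0)
  t0 <- tidy(relative_expression(g0$ct, "sgCtrl"))
  expect_equal(
    t0$mean_fold[match(g0$truth$group, t0$group)],
    g0$truth$true_fold
  )
  # noisy replicate tables recover each planted fold within 3 standard errors
  n_rep <- 100
  est <- matrix(NA_real_, n_rep, 3)
  for (r in seq_len(n_rep)) {
    g <- generate_ct_table(sim_config(seed = 1000 + r))
    tg <- tidy(relative_expression(g$ct, "sgCtrl"))
    est[r, ] <- tg$mean_fold[match(c("kd20", "kd50", "kd80"), tg$group)]
  }
  truth <- c(0.8, 0.5, 0.2)
  for (j in 1:3) {
    se <- sd(est[, j]) / sqrt(n_rep)
    expect_lt(abs(mean(est[, j]) - truth[j]), 3 * se + 1e-12)
  }
})

test_that("pairwise Bonferroni threshold follows 2a/k(k-1)", {
  expect_equal(pairwise_alpha(0.05, 5), 0.005)
  expect_equal(round(pairwise_alpha(0.05, 6), 4), 0.0033)
  expect_equal(pairwise_alpha(0.05, 2), 0.05) # single comparison
  expect_equal(pairwise_alpha(0.05, 4), 0.05 / choose(4, 2))
  # strictly decreasing in k, linear in alpha
  ks <- 2:10
  expect_true(all(diff(pairwise_alpha(0.05, ks)) < 0))
  expect_equal(pairwise_alpha(0.02, 5), 0.4 * pairwise_alpha(0.05, 5))
  expect_error(pairwise_alpha(0.05, 1), ">= 2")
  expect_error(pairwise_alpha(1.2, 3), "0, 1")
})

test_that("survival rate is the plain ratio with guarded inputs", {
  expect_equal(survival_rate(100, 100), 1)
  expect_equal(survival_rate(0, 150), 0)
  expect_equal(survival_rate(53, 106), 0.5)
  expect_error(survival_rate(5, 0), "positive")
  expect_error(survival_rate(7, 5), "<=")
})

test_that("threshold masks honour inclusive bounds and are monotone", {
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 150
  img[, , 2] <- 90
  img[, , 3] <- 60
  full <- list(R = c(0, 255), G = c(0, 255), B = c(0, 255))
  expect_true(all(threshold_mask(img, full)))
  off <- list(R = c(0, 149), G = c(0, 255), B = c(0, 255))
  expect_false(any(threshold_mask(img, off)))
  edge <- list(R = c(150, 150), G = c(90, 90), B = c(60, 60))
  expect_true(all(threshold_mask(img, edge))) # inclusive bounds
  # widening any channel bound never shrinks the mask
  withr::local_seed(19)
  rnd <- array(sample(0:255, 4 * 4 * 3, replace = TRUE), dim = c(4, 4, 3))
  b1 <- list(R = c(60, 180), G = c(40, 200), B = c(20, 220))
  m1 <- threshold_mask(rnd, b1)
  for (chan in c("R", "G", "B")) {
    b2 <- b1
    b2[[chan]] <- c(b1[[chan]][1] - 20, b1[[chan]][2] + 20)
    expect_true(all(m1 <= threshold_mask(rnd, b2)))
  }
  expect_error(threshold_mask(rnd, list(R = c(-1, 255), G = c(0, 255), B = c(0, 255))), "0-255")
})

test_that("hemoglobin index divides positive pixels by yolk pixels", {
  yolk <- matrix(FALSE, 10, 10)
  yolk[3:7, 3:7] <- TRUE # 25 px
  pos <- matrix(FALSE, 10, 10)
  pos[3:7, 3] <- TRUE # 5 px inside yolk
  q <- hemoglobin_index(pos, yolk)
  expect_equal(q$hemoglobin_index, 5 / 25)
  expect_equal(hemoglobin_index(yolk, yolk)$hemoglobin_index, 1)
  expect_equal(hemoglobin_index(matrix(FALSE, 10, 10), yolk)$hemoglobin_index, 0)
  # positive pixels outside the yolk are excluded under the default
  pos_out <- pos
  pos_out[1, 1] <- TRUE
  expect_equal(hemoglobin_index(pos_out, yolk)$positive_pixels, 5)
  expect_equal(hemoglobin_index(pos_out, yolk, restrict_to_yolk = FALSE)$positive_pixels, 6)
  expect_error(hemoglobin_index(pos, matrix(FALSE, 10, 10)), "empty")
})

test_that("PNG image round trip preserves the 0-255 RGB array", {
  withr::local_seed(8)
  img <- array(sample(0:255, 12 * 9 * 3, replace = TRUE), dim = c(12, 9, 3))
  path <- withr::local_tempfile(fileext = ".png")
  write_rgb_image(img, path)
  expect_equal(read_rgb_image(path), img, ignore_attr = TRUE)
})
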