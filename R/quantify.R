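# Quantification formulas used downstream of the CRISPRi perturbations:
# 2^-ddCt relative expression, the pairwise Bonferroni-adjusted threshold,
# survival rate, and stained-area quantification from thresholded masks.

#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification from qPCR cycle thresholds against a
#' reference gene (beta-actin in the motivating assays) and a calibrator
#' group. Per sample, dCt = target_ct - reference_ct; ddCt = dCt minus the
#' arithmetic mean dCt of the calibrator group; fold change = 2^-ddCt. The
#' calibrator group's geometric-mean fold is therefore exactly 1.
#'
#' @param ct Tibble with `sample_id`, `group`, `target_ct`, `reference_ct`
#'   (cycles, each in (0, 45)).
#' @param calibrator_group Name of the calibrator (control) group; must be
#'   present in `ct$group`.
#' @return A `ddct_fit` object; [tidy()] gives per-group mean fold with SEM,
#'   `$samples` holds the per-sample table (`delta_ct`, `delta_delta_ct`,
#'   `fold_change`).
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = c("c1", "c2", "t1", "t2"), group = c("ctrl", "ctrl", "kd", "kd"),
#'   target_ct = c(20, 20, 21, 21), reference_ct = c(15, 15, 15, 15)
#' )
#' tidy(relative_expression(ct, "ctrl")) # kd fold 0.5
#' @export
relative_expression <- function(ct, calibrator_group) {
  ct <- as_tibble(ct)
  req <- c("sample_id", "group", "target_ct", "reference_ct")
  if (!all(req %in% names(ct))) {
    abort(paste0("ct table needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(ct$target_ct <= 0 | ct$target_ct >= 45 |
    ct$reference_ct <= 0 | ct$reference_ct >= 45)) {
    abort("Ct values must lie in (0, 45) cycles")
  }
  if (!calibrator_group %in% ct$group) {
    abort(paste0("calibrator group not present in data: ", calibrator_group))
  }
  samples <- mutate(ct, delta_ct = .data$target_ct - .data$reference_ct)
  cal_mean <- mean(samples$delta_ct[samples$group == calibrator_group])
  samples <- mutate(
    samples,
    delta_delta_ct = .data$delta_ct - cal_mean,
    fold_change = 2^(-.data$delta_delta_ct)
  )
  groups <- samples |>
    group_by(.data$group) |>
    summarise(
      n = dplyr::n(),
      mean_fold = mean(.data$fold_change),
      sem_fold = stats::sd(.data$fold_change) / sqrt(dplyr::n()),
      mean_delta_delta_ct = mean(.data$delta_delta_ct),
      .groups = "drop"
    ) |>
    mutate(is_calibrator = .data$group == calibrator_group)
  structure(
    list(
      samples = samples, groups = groups,
      calibrator_group = calibrator_group
    ),
    class = "ddct_fit"
  )
}

#' @export
print.ddct_fit <- function(x, ...) {
  cat(sprintf(
    "2^-ddCt fit: %d samples in %d groups (calibrator: %s)\n",
    nrow(x$samples), nrow(x$groups), x$calibrator_group
  ))
  print(x$groups)
  invisible(x)
}

#' @describeIn relative_expression Per-group fold-change summary.
#' @param x A `ddct_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ddct_fit <- function(x, ...) x$groups

#' @describeIn relative_expression One-row overview (groups, samples,
#'   calibrator).
#' @exportS3Method generics::glance
glance.ddct_fit <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    n_groups = nrow(x$groups),
    calibrator_group = x$calibrator_group
  )
}

#' @describeIn relative_expression Mean fold change per group with SEM bars.
#' @param object A `ddct_fit` object.
#' @exportS3Method ggplot2::autoplot
autoplot.ddct_fit <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$group, y = .data$mean_fold)) +
    geom_col(fill = "grey70") +
    geom_errorbar(
      aes(
        ymin = .data$mean_fold - .data$sem_fold,
        ymax = .data$mean_fold + .data$sem_fold
      ),
      width = 0.2
    ) +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = NULL, y = "relative expression (2^-ddCt)") +
    theme_bw()
}

#' Pairwise Bonferroni-adjusted significance threshold
#'
#' For post hoc pairwise comparisons among `k` groups at family-wise level
#' `alpha`, the per-comparison threshold is `2 * alpha / (k * (k - 1))`,
#' i.e. alpha divided by the number of pairs choose(k, 2). With `k = 2` it
#' reduces to `alpha`.
#'
#' @param alpha Family-wise significance level in (0, 1); default 0.05.
#' @param k Number of groups compared (integer >= 2); vectorized.
#' @return Adjusted per-comparison threshold(s).
#' @examples
#' pairwise_alpha(0.05, 5) # 0.005
#' pairwise_alpha(0.05, 6) # 0.00333...
#' @export
pairwise_alpha <- function(alpha = 0.05, k) {
  if (any(alpha <= 0 | alpha >= 1)) abort("alpha must lie in (0, 1)")
  if (any(k < 2 | k != as.integer(k))) abort("k must be an integer >= 2")
  2 * alpha / (k * (k - 1))
}

#' Survival rate
#'
#' Ratio of surviving embryos to the total number of embryos; vectorized.
#'
#' @param n_survivors,n_total Counts with `0 <= n_survivors <= n_total`,
#'   `n_total > 0`.
#' @return Survival proportion(s) in `[0, 1]`.
#' @export
survival_rate <- function(n_survivors, n_total) {
  if (any(n_total <= 0)) abort("n_total must be positive")
  if (any(n_survivors < 0 | n_survivors > n_total)) {
    abort("need 0 <= n_survivors <= n_total")
  }
  n_survivors / n_total
}

#' Threshold an RGB image into a binary mask
#'
#' A pixel enters the mask iff every channel value lies within its inclusive
#' `[min, max]` bounds - the batch color-threshold operation used to isolate
#' the brown peroxidase stain. Bounds must be explicit per channel; a
#' published single-value setting (e.g. B = 105, G = 150, R = 190) should be
#' turned into explicit bounds by the analyst because the thresholding
#' direction is not implied by the values alone.
#'
#' @param image 8-bit RGB array of shape (height, width, 3), values 0-255
#'   (see [read_rgb_image()]).
#' @param bounds Named list with elements `R`, `G`, `B`, each `c(min, max)`
#'   within 0-255.
#' @return Logical matrix (height x width).
#' @export
threshold_mask <- function(image, bounds) {
  if (length(dim(image)) != 3 || dim(image)[3] < 3) {
    abort("image must be an array of shape (height, width, 3)")
  }
  if (!all(c("R", "G", "B") %in% names(bounds))) {
    abort("bounds must name channels R, G, B")
  }
  for (chan in c("R", "G", "B")) {
    b <- bounds[[chan]]
    if (length(b) != 2 || any(b < 0 | b > 255) || b[1] > b[2]) {
      abort(paste0("bounds for channel ", chan, " must be c(min, max) within 0-255"))
    }
  }
  ch <- function(i) image[, , i]
  (ch(1) >= bounds$R[1] & ch(1) <= bounds$R[2]) &
    (ch(2) >= bounds$G[1] & ch(2) <= bounds$G[2]) &
    (ch(3) >= bounds$B[1] & ch(3) <= bounds$B[2])
}

#' Hemoglobin index from stain and yolk masks
#'
#' Stained-area quantification: hemoglobin-positive pixel count divided by
#' yolk-sac pixel count, both taken from binary masks of the same image.
#'
#' @param positive_mask Logical matrix marking stain-positive pixels.
#' @param yolk_mask Logical matrix (same shape) marking the yolk sac; must be
#'   non-empty.
#' @param restrict_to_yolk Count only positive pixels inside the yolk mask
#'   (default `TRUE`; both areas are measured on the same embryo image).
#' @return One-row tibble: `positive_pixels`, `yolk_pixels`,
#'   `hemoglobin_index`.
#' @export
hemoglobin_index <- function(positive_mask, yolk_mask, restrict_to_yolk = TRUE) {
  if (!identical(dim(positive_mask), dim(yolk_mask))) {
    abort("masks must have identical dimensions")
  }
  yolk_pixels <- sum(yolk_mask)
  if (yolk_pixels == 0) abort("yolk mask is empty")
  positive_pixels <- if (restrict_to_yolk) {
    sum(positive_mask & yolk_mask)
  } else {
    sum(positive_mask)
  }
  tibble(
    positive_pixels = positive_pixels,
    yolk_pixels = yolk_pixels,
    hemoglobin_index = positive_pixels / yolk_pixels
  )
}

#' Read an RGB image into a 0-255 array
#'
#' @param path PNG path.
#' @return Numeric array (height, width, 3) with values on the 0-255 scale.
#' @export
read_rgb_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    img <- array(rep(img, 3), dim = c(dim(img), 3))
  }
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Write a 0-255 RGB array as PNG
#'
#' @param image Array (height, width, 3), values 0-255.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}
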