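# Loop annotation against classified regulatory elements and EP-loop calling.
#
# A loop is an anchor pair; each anchor picks up the classes of every element
# it overlaps (>= 1 bp, no padding by default). Categories, by precedence:
#   EP  - one anchor overlaps a promoter, the other an enhancer
#   PP  - both anchors overlap promoters (and no EP configuration exists)
#   EE  - both anchors overlap enhancers
#   PN / EN - exactly one anchor annotated
#   NN  - neither anchor overlaps any element

loop_categories <- c("EP", "PP", "EE", "PN", "EN", "NN")

#' Annotate loops against regulatory elements
#'
#' Overlaps each loop anchor with the classified elements and assigns each
#' loop exactly one category (`EP`, `PP`, `EE`, `PN`, `EN`, `NN`, by that
#' precedence). An anchor carrying both a promoter and an enhancer does not
#' block an EP call; the loop is flagged `ambiguous` instead. Inter-chromosomal
#' loops are annotated like any other but get no distance.
#'
#' @param loops Loop tibble (see [read_loops()]); a `loop_id` column is added
#'   if absent.
#' @param elements Element tibble from [classify_elements()].
#' @param padding Symmetric anchor padding in bp applied before overlap;
#'   default 0 (no slop).
#' @return The loop tibble with added columns `loop_id`, `promoters_a`,
#'   `enhancers_a`, `promoters_b`, `enhancers_b` (comma-joined element ids,
#'   `""` if none), `category`, `ambiguous`, and `distance_bp` (midpoint to
#'   midpoint; `NA` for inter-chromosomal loops), ordered by (chrom, start).
#' @export
annotate_loops <- function(loops, elements, padding = 0) {
  if (padding < 0) abort("padding must be non-negative")
  loops <- as_tibble(loops)
  if (!"loop_id" %in% names(loops)) {
    loops$loop_id <- sprintf("loop_%04d", seq_len(nrow(loops)))
  }
  if (nrow(loops) == 0) {
    out <- loops
    out$promoters_a <- character()
    out$enhancers_a <- character()
    out$promoters_b <- character()
    out$enhancers_b <- character()
    out$category <- character()
    out$ambiguous <- logical()
    out$distance_bp <- double()
    return(out)
  }
  anchor_hits <- function(side) {
    a <- tibble(
      chrom = loops[[paste0("chrom_", side)]],
      start = pmax(0, loops[[paste0("start_", side)]] - padding),
      end = loops[[paste0("end_", side)]] + padding
    )
    hits <- overlap_join(a, elements)
    ids_of <- function(cls) {
      vapply(seq_len(nrow(loops)), function(i) {
        j <- hits$y_idx[hits$x_idx == i]
        j <- j[elements$element_class[j] == cls]
        paste(elements$element_id[j], collapse = ",")
      }, character(1))
    }
    list(promoters = ids_of("promoter"), enhancers = ids_of("enhancer"))
  }
  ha <- anchor_hits("a")
  hb <- anchor_hits("b")
  p_a <- nzchar(ha$promoters)
  e_a <- nzchar(ha$enhancers)
  p_b <- nzchar(hb$promoters)
  e_b <- nzchar(hb$enhancers)
  category <- dplyr::case_when(
    (p_a & e_b) | (e_a & p_b) ~ "EP",
    p_a & p_b ~ "PP",
    e_a & e_b ~ "EE",
    p_a | p_b ~ "PN",
    e_a | e_b ~ "EN",
    TRUE ~ "NN"
  )
  loops |>
    mutate(
      promoters_a = ha$promoters, enhancers_a = ha$enhancers,
      promoters_b = hb$promoters, enhancers_b = hb$enhancers,
      category = factor(category, levels = loop_categories),
      ambiguous = (p_a & e_a) | (p_b & e_b),
      distance_bp = ifelse(
        .data$chrom_a == .data$chrom_b,
        abs((.data$start_b + .data$end_b) / 2 - (.data$start_a + .data$end_a) / 2),
        NA_real_
      )
    ) |>
    arrange(.data$chrom_a, .data$start_a, .data$chrom_b, .data$start_b)
}

#' Call EP-loops
#'
#' Runs [annotate_loops()] and packages the full annotation table together
#' with the EP subset as an `ep_annotation` object with [tidy()], [glance()]
#' and [autoplot()] methods.
#'
#' @inheritParams annotate_loops
#' @return An object of class `ep_annotation`: list with `annotation` (every
#'   input loop, one category each), `ep_loops` (the EP subset) and
#'   `elements`.
#' @export
call_ep_loops <- function(loops, elements, padding = 0) {
  ann <- annotate_loops(loops, elements, padding = padding)
  structure(
    list(
      annotation = ann,
      ep_loops = filter(ann, .data$category == "EP"),
      elements = elements
    ),
    class = "ep_annotation"
  )
}

#' @export
print.ep_annotation <- function(x, ...) {
  cat(sprintf(
    "EP-loop annotation: %d loops, %d EP (%d promoters, %d enhancers)\n",
    nrow(x$annotation), nrow(x$ep_loops),
    sum(x$elements$element_class == "promoter"),
    sum(x$elements$element_class == "enhancer")
  ))
  invisible(x)
}

#' @describeIn call_ep_loops Full per-loop annotation table.
#' @param x An `ep_annotation` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.ep_annotation <- function(x, ...) x$annotation

#' @describeIn call_ep_loops One-row summary: loop counts per category,
#'   total loops and median EP distance.
#' @exportS3Method generics::glance
glance.ep_annotation <- function(x, ...) {
  counts <- table(factor(x$annotation$category, levels = loop_categories))
  out <- as_tibble(as.list(setNames(as.integer(counts), paste0("n_", names(counts)))))
  out$n_loops <- nrow(x$annotation)
  out$median_ep_distance_bp <- stats::median(x$ep_loops$distance_bp, na.rm = TRUE)
  out
}

#' Per-chromosome EP vs non-EP loop counts
#'
#' Tallies, for each chromosome (taken from the first anchor), how many loops
#' are EP and how many are not. Counts sum to the number of input loops.
#'
#' @param annotation Annotation tibble from [annotate_loops()] or an
#'   `ep_annotation` object.
#' @return Tibble with `chrom`, `n_ep`, `n_non_ep`, `n_total`.
#' @export
summarize_by_chromosome <- function(annotation) {
  if (inherits(annotation, "ep_annotation")) annotation <- annotation$annotation
  annotation |>
    group_by(chrom = .data$chrom_a) |>
    summarise(
      n_ep = sum(.data$category == "EP"),
      n_non_ep = sum(.data$category != "EP"),
      .groups = "drop"
    ) |>
    mutate(n_total = .data$n_ep + .data$n_non_ep) |>
    arrange(.data$chrom)
}

#' @describeIn call_ep_loops Stacked per-chromosome bar chart of EP vs non-EP
#'   loop counts.
#' @param object An `ep_annotation` object.
#' @exportS3Method ggplot2::autoplot
autoplot.ep_annotation <- function(object, ...) {
  summarize_by_chromosome(object) |>
    tidyr::pivot_longer(c("n_ep", "n_non_ep"),
      names_to = "class", values_to = "n"
    ) |>
    mutate(class = ifelse(.data$class == "n_ep", "EP", "non-EP")) |>
    ggplot(aes(x = .data$chrom, y = .data$n, fill = .data$class)) +
    geom_col(position = position_stack()) +
    scale_fill_manual(values = c("EP" = "#E69F00", "non-EP" = "#FFF2CC")) +
    labs(x = NULL, y = "loops", fill = NULL) +
    theme_bw()
}
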