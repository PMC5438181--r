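#' Plot a %MinMax profile
#'
#' Score per window along the coding sequence, with rare codon clusters
#' (runs of negative windows) shaded and cluster peaks marked.
#'
#' @param object A profile from [minmax_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.minmax_profile <- function(object, ...) {
  cl <- detect_clusters(object)
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$window_start, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "codon position (window anchor)", y = "%MinMax",
      title = object$gene_id[1]
    ) +
    ggplot2::theme_minimal()
  if (nrow(cl) > 0) {
    shade <- tibble(
      xmin = object$window_start[match(cl$start_window, object$window)],
      xmax = object$window_start[match(cl$end_window, object$window)]
    )
    p <- p +
      ggplot2::geom_rect(
        data = shade,
        ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = 0),
        inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
      ) +
      ggplot2::geom_point(
        data = tibble(x = cl$peak_codon, y = cl$peak_score),
        ggplot2::aes(x = .data$x, y = .data$y),
        inherit.aes = FALSE, colour = "firebrick"
      )
  }
  p
}

#' Plot the significance funnel of an analysis
#'
#' Number of homolog families with significant co-occurrence at each stage
#' of the pipeline: raw, after RRT masking, after masking plus terminal
#' trimming.
#'
#' @param object A `crcc_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crcc_analysis <- function(object, ...) {
  g <- glance(object)
  df <- tibble(
    stage = factor(
      c("co-occurrence", "+ RRT masking", "+ trimming"),
      levels = c("co-occurrence", "+ RRT masking", "+ trimming")
    ),
    families = c(g$n_sig_pre_rrt, g$n_sig_post_rrt, g$n_sig_post_trim)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$families)) +
    ggplot2::geom_col(fill = "grey25") +
    ggplot2::labs(x = NULL, y = "significant homolog families") +
    ggplot2::theme_minimal()
}

#' Per-column co-occurrence p-values of one family
#'
#' @param stats A column-stat tibble (one family), flags applied.
#' @param threshold Significance threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_column_pvalues <- function(stats, threshold = 1e-4) {
  df <- mutate(
    stats,
    status = dplyr::case_when(
      .data$gap_excluded ~ "gap-excluded",
      .data$rrt_masked ~ "RRT-masked",
      .data$trimmed ~ "trimmed",
      TRUE ~ "tested"
    )
  )
  ggplot2::ggplot(
    df[!is.na(df$p_value), ],
    ggplot2::aes(x = .data$column, y = -log10(.data$p_value), colour = .data$status)
  ) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::labs(
      x = "alignment column", y = "-log10 p",
      title = stats$family_id[1], colour = NULL
    ) +
    ggplot2::theme_minimal()
}
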