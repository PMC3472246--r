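#' Plot selection-frequency profile of a signature
#'
#' Rank-ordered selection frequencies with the signature cutoff `N` marked.
#'
#' @param object A `glucose_signature`.
#' @param max_rank Truncate the x axis (default: twice `N`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.glucose_signature <- function(object, max_rank = 2 * object$N,
                                       ...) {
  df <- dplyr::filter(object$genes, .data$rank <= max_rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank,
                                   y = .data$frequency / object$config$n_repeats)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$N + 0.5, linetype = "dashed") +
    ggplot2::labs(x = "gene rank by selection frequency",
                  y = "selection frequency",
                  title = sprintf("glucose signature (N = %d)", object$N)) +
    ggplot2::theme_minimal()
}

#' Plot a hierarchical transcription network
#'
#' Vertices are placed on a vertical axis by downstream score (incoming
#' minus outgoing sequential edges); edges are drawn as segments coloured
#' by type, sequential edges solid and non-sequential dashed.
#'
#' @param object A `hierarchy_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hierarchy_network <- function(object, ...) {
  rk <- downstream_ranking(object)
  pos <- tibble::tibble(
    mutant = rk$mutant,
    xpos = seq_along(rk$mutant),
    ypos = rk$score
  )
  p <- ggplot2::ggplot(pos, ggplot2::aes(x = .data$xpos, y = .data$ypos)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$mutant), vjust = -1,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "downstream score (in - out, sequential)",
                  title = "hierarchical transcription network") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (nrow(object$edges) > 0) {
    seg <- dplyr::left_join(object$edges, pos, by = c(x = "mutant"))
    seg <- dplyr::left_join(seg, pos, by = c(y = "mutant"),
                            suffix = c("", "_end"))
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$xpos, y = .data$ypos, xend = .data$xpos_end,
                   yend = .data$ypos_end, colour = .data$type,
                   linetype = .data$category),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      alpha = 0.7, inherit.aes = FALSE
    )
  }
  p
}

#' Plot mean signature trajectories of a time-course
#'
#' @param object A [timecourse_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.timecourse_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$mean_logfc,
                                       colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_logfc - .data$sd_logfc,
                   ymax = .data$mean_logfc + .data$sd_logfc,
                   fill = .data$set),
      alpha = 0.15, colour = NA
    ) +
    ggplot2::labs(x = "minutes after glucose addition",
                  y = "mean log2 fold-change", colour = "gene set",
                  fill = "gene set") +
    ggplot2::theme_minimal()
}

#' Plot an epistasis verdict
#'
#' Bar chart of the double mutant's similarity to each parent with the
#' dominance margin annotated.
#'
#' @param object An `epistasis_verdict`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epistasis_verdict <- function(object, ...) {
  df <- tibble::tibble(
    parent = names(object$similarity_to_parent),
    similarity = unname(object$similarity_to_parent)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parent, y = .data$similarity)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(
      x = NULL, y = "cosine similarity to double mutant",
      title = sprintf("%s: dominant = %s (margin %.2f)", object$double_id,
                      object$dominant, object$margin)
    ) +
    ggplot2::theme_minimal()
}
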