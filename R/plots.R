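#' Plot item characteristic curves of a fit
#'
#' One logistic curve per item over the ability scale, showing the guessing
#' floor and, for a 2PL fit, the spread of slopes; curves are colored by
#' easiness so the difficulty gradient is visible at a glance.
#'
#' @param object An `irt_fit`.
#' @param theta_range Ability range to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.irt_fit <- function(object, theta_range = c(-4, 4), ...) {
  grid <- tidyr::expand_grid(
    object$items[, c("item_id", "easiness", "discrimination")],
    theta = seq(theta_range[1], theta_range[2], length.out = 101)
  )
  grid$p <- eval_icc(grid$theta, grid$easiness, grid$discrimination,
                     object$guessing)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$theta, y = .data$p,
                                     group = .data$item_id,
                                     colour = .data$easiness)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$guessing, linetype = "dashed") +
    ggplot2::labs(x = "ability (logits)", y = "P(correct)",
                  colour = "easiness",
                  title = sprintf("Item characteristic curves (%s)",
                                  object$model)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot an annealing trace
#'
#' Current and best-so-far objective against iteration, the standard way to
#' audit that the search cooled into hill climbing and plateaued.
#'
#' @param object A `subset_solution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subset_solution <- function(object, ...) {
  tr <- tidyr::pivot_longer(object$trace,
                            cols = c("objective", "best_objective"),
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iter, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "proposal", y = "objective",
                  title = sprintf("Annealing trace (size %d)", object$size)) +
    ggplot2::theme_minimal()
}

#' Plot group-specific easiness from a DIF analysis
#'
#' Per-item easiness with 95% intervals for each group; flagged items
#' (non-overlapping intervals) are marked.
#'
#' @param object A `dif_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dif_result <- function(object, ...) {
  gr <- attr(object, "groups")
  df <- tibble::as_tibble(as.data.frame(object))
  long <- dplyr::bind_rows(
    tibble::tibble(item_id = df$item_id, group = gr[1],
                   easiness = df$easiness_1, lwr = df$lwr_1, upr = df$upr_1,
                   flagged = !df$intervals_overlap),
    tibble::tibble(item_id = df$item_id, group = gr[2],
                   easiness = df$easiness_2, lwr = df$lwr_2, upr = df$upr_2,
                   flagged = !df$intervals_overlap)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$item_id, y = .data$easiness,
                                     colour = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lwr,
                                          ymax = .data$upr),
                             position = ggplot2::position_dodge(width = 0.5),
                             fatten = 1.5) +
    ggplot2::geom_point(data = dplyr::filter(long, .data$flagged),
                        shape = 8, colour = "black") +
    ggplot2::labs(x = NULL, y = "easiness (logits)",
                  title = sprintf("Group-specific easiness (%s), r = %.3f",
                                  attr(object, "grouping"),
                                  attr(object, "group_correlation"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot a size sweep
#'
#' Two facets mirroring the evidence used to pick a short-form length: the
#' Rasch-vs-2PL comparison ratio by subset size (dashed line at 1), and the
#' subset/full-pool sum-score correlation by stratum.
#'
#' @param sweep Output of [size_sweep()].
#' @return A ggplot object.
#' @export
plot_size_sweep <- function(sweep) {
  ratio_df <- dplyr::distinct(sweep, .data$size, .data$run,
                              .keep_all = TRUE)
  ratio_df$panel <- "model comparison ratio"
  ratio_df$value <- ratio_df$ratio
  corr_df <- sweep
  corr_df$panel <- "subset vs full-task correlation"
  corr_df$value <- corr_df$r
  df <- dplyr::bind_rows(
    ratio_df[, c("size", "run", "panel", "value")] |>
      dplyr::mutate(stratum = "overall"),
    corr_df[, c("size", "run", "panel", "value", "stratum")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$value,
                                   colour = .data$stratum)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::geom_hline(
      data = data.frame(panel = "model comparison ratio", y = 1),
      ggplot2::aes(yintercept = .data$y), linetype = "dashed",
      inherit.aes = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "subset size", y = NULL) +
    ggplot2::theme_minimal()
}
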