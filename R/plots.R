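slice_map_points <- function(maps, layers, label) {
  pts <- bind_rows(imap(maps, function(g, i) {
    if (length(g) == 0) return(NULL)
    bind_cols(tibble(slice = i), decode_gid(g, layers))
  }))
  if (nrow(pts) == 0) {
    return(tibble(slice = integer(), x = numeric(), y = numeric(),
                  layer = character(), set = character()))
  }
  pts |>
    mutate(
      x = if_else(.data$layer == "M1",
                  (neuron_coords(.data$neuron_id)$block %% 2) * 13 +
                    neuron_coords(.data$neuron_id)$col,
                  .data$neuron_id %% 26),
      y = if_else(.data$layer == "M1",
                  -((neuron_coords(.data$neuron_id)$block %/% 2) * 13 +
                      neuron_coords(.data$neuron_id)$row),
                  -28 - .data$neuron_id %/% 26),
      set = label
    )
}

#' Plot sliced spike maps as dot rasters
#'
#' One panel per time slice; M1 neurons are laid out as the four 12x12
#' feature blocks in a 2x2 arrangement, M2 neurons (if any) as rows below.
#'
#' @param object A `slice_maps` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.slice_maps <- function(object, ...) {
  pts <- slice_map_points(object$maps, object$layers, "active")
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 1.2, colour = "grey25") +
    ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Active neurons per time slice")
}

#' @exportS3Method ggplot2::autoplot
autoplot.snn_expression <- function(object, ...) {
  pts <- slice_map_points(object$maps, object$layers, "expression")
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(size = 1.2, colour = "grey25") +
    ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("Expression of class %s", object$digit))
}

#' Overlay a sample on a class expression
#'
#' Neurons active in both the expression and the sample are grey, neurons
#' only in the expression red, neurons only in the sample green -- the
#' visual form of the per-slice Jaccard comparison.
#'
#' @param expression An `snn_expression`.
#' @param sample A `slice_maps` with the same scheme.
#' @return A ggplot object.
#' @export
plot_expression_match <- function(expression, sample) {
  n <- length(expression$maps)
  stopifnot(length(sample$maps) == n)
  pts <- bind_rows(map(seq_len(n), function(i) {
    e <- expression$maps[[i]]
    s <- sample$maps[[i]]
    groups <- list(
      both = intersect(e, s),
      `expression only` = setdiff(e, s),
      `sample only` = setdiff(s, e)
    )
    bind_rows(imap(groups, function(g, lbl) {
      slice_map_points(stats::setNames(list(g), NULL), expression$layers, lbl) |>
        mutate(slice = i)
    }))
  }))
  ggplot2::ggplot(pts, ggplot2::aes(.data$x, .data$y, colour = .data$set)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::scale_colour_manual(values = c(
      both = "grey50", `expression only` = "red3", `sample only` = "green4"
    )) +
    ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.pairslice_run <- function(object, ...) {
  res <- tidy(object)
  ggplot2::ggplot(res, ggplot2::aes(.data$n_slices, .data$accuracy,
                                    colour = factor(.data$freq_threshold))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(res$n_slices)) +
    ggplot2::labs(x = "time slices", y = "test accuracy",
                  colour = "freq threshold") +
    ggplot2::theme_minimal()
}
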