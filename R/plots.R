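# autoplot methods for the main result types.

#' @export
#' @method autoplot plasmasig_catalogue
autoplot.plasmasig_catalogue <- function(object, ...) {
  scheme <- attr(object, "scheme")
  df <- as_tibble(object)
  df$channel <- factor(df$channel, levels = df$channel)
  df$group <- switch(scheme,
    SBS96 = sub(".*\\[(.+)\\].*", "\\1", df$channel),
    DBS78 = sub(">.*", "", df$channel),
    ID83 = sub("^([0-9]+:[A-Za-z]+:[A-Z]).*", "\\1", df$channel)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$channel, y = .data$count,
                                   fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_grid(. ~ group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "mutations",
                  title = sprintf("%s catalogue: %s", scheme,
                                  attr(object, "sample"))) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 4))
}

#' @export
#' @method autoplot plasmasig_fit
autoplot.plasmasig_fit <- function(object, min_weight = 0.005, ...) {
  df <- object$weights %>% filter(.data$weight >= min_weight)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$signature,
                                                      -.data$weight),
                                   y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "signature weight",
                  title = sprintf("%s (%g mutations)", object$sample,
                                  object$total)) +
    ggplot2::theme_minimal()
}

#' @export
#' @method autoplot plasmasig_thresholds
autoplot.plasmasig_thresholds <- function(object, ...) {
  df <- object$thresholds
  ggplot2::ggplot(df, ggplot2::aes(x = .data$signature,
                                   y = .data$threshold)) +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(x = NULL,
                  y = sprintf("detection threshold (q = %.2f)", object$q)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
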