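#' Plot a concentration-response fit
#'
#' Points per replicate well, the three candidate curves (winner solid,
#' losers dashed), the efficacy cutoff band when supplied, and a log10
#' concentration axis.
#'
#' @param object A `devtox_fit`.
#' @param coff Optional efficacy cutoff to draw as a baseline band.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.devtox_fit <- function(object, coff = NULL, ...) {
  xr <- range(object$data$logc)
  grid <- tibble(logc = seq(xr[1] - 0.25, xr[2] + 0.25, length.out = 200))
  curves <- object$fits |>
    filter(.data$converged) |>
    purrr::pmap_dfr(function(model, params, winner, ...) {
      par <- unlist(params)
      resp <- model_mu[[model]](grid$logc, par[model_par_names[[model]]])
      tibble(model = model, winner = winner, logc = grid$logc, resp = resp)
    })
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$logc, y = .data$resp)) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$model,
                                    linetype = .data$winner, group = .data$model)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::labs(x = "log10 concentration (uM)", y = "response (%)",
                  colour = "model") +
    ggplot2::theme_minimal()
  if (!is.null(coff)) {
    p <- p + ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                               ymin = -coff, ymax = coff, alpha = 0.12) +
      ggplot2::geom_hline(yintercept = coff, linetype = "dotted")
  }
  p
}

#' Plot per-plate QC metrics
#'
#' Dot plot of the robust Z'-factor per plate with the 0.5 screening-quality
#' line.
#'
#' @param qc Result of [plate_qc()].
#' @return A ggplot object.
#' @export
plot_plate_qc <- function(qc) {
  ggplot2::ggplot(qc$per_plate,
                  ggplot2::aes(x = .data$plate_id, y = .data$rzprime)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "robust Z'-factor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
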