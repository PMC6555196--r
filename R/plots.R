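#' Plot simulation results
#'
#' Membrane-potential traces at selected segments over time; with
#' `what = "vout"`, the extracellular potentials instead.
#'
#' @param object a `ephapsis_result`.
#' @param segments segment ids to plot (default: middle segment of each
#'   cell).
#' @param what `"vm"` or `"vout"`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ephapsis_result <- function(object, segments = NULL,
                                     what = c("vm", "vout"), ...) {
  what <- match.arg(what)
  if (is.null(segments)) {
    segments <- vapply(sort(unique(object$segments$cell_index)), function(ci) {
      ids <- object$segments$id[object$segments$cell_index == ci]
      ids[ceiling(length(ids) / 2)]
    }, 1L)
  }
  df <- tidy(object, segments = segments)
  df$trace <- paste0(df$cell, "/", df$section, "[", df$segment, "]")
  yv <- if (what == "vout") "vout" else "vm"
  ylab <- if (what == "vout") "extracellular potential (mV)" else
    "membrane potential (mV)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data[[yv]],
                                   colour = .data$trace)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (ms)", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-correlation function
#'
#' @param object a `ephapsis_xcorr`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ephapsis_xcorr <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_ms, y = .data$value)) +
    ggplot2::geom_col(width = attr(object, "bin_width") * 0.9) +
    ggplot2::labs(x = "lag (ms)", y = "correlation") +
    ggplot2::theme_minimal()
}

#' Plot a phase-locking summary
#'
#' Mean +- SD cross-correlation function across pairs and runs.
#'
#' @param object a `ephapsis_locking`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ephapsis_locking <- function(object, ...) {
  df <- object$mean_cc
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lag_ms, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms)", y = "mean cross-correlation",
                  title = paste0("condition: ", format(object$condition))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
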