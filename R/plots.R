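#' Plot an ECDF of maximum lengths
#'
#' @param object a \code{\link{ecdf_max_length}} result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.filo_ecdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$max_length_um,
                                       y = .data$proportion)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "maximum length (µm)",
                  y = "proportion of filopodia ≤ length") +
    ggplot2::ylim(0, 1)
}

#' Plot the exponential diagnostic
#'
#' Empirical cumulative distribution of the observed maximum lengths with
#' the fitted shifted-exponential CDF overlaid.
#'
#' @param object a \code{\link{exponential_diagnostic}} fit.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.filo_expfit <- function(object, ...) {
  emp <- ecdf_max_length(object$sample)
  xs <- seq(object$offset, max(object$sample), length.out = 200)
  fit <- tibble::tibble(x = xs,
                        p = stats::pexp(xs - object$offset, object$rate))
  ggplot2::ggplot() +
    ggplot2::geom_step(data = emp,
                       ggplot2::aes(x = .data$max_length_um,
                                    y = .data$proportion)) +
    ggplot2::geom_line(data = fit,
                       ggplot2::aes(x = .data$x, y = .data$p),
                       linetype = 2, colour = "red") +
    ggplot2::labs(x = "maximum length (µm)", y = "cumulative proportion",
                  subtitle = sprintf("rate %.3g/µm, KS %.3f",
                                     object$rate, object$ks_statistic))
}

#' Plot per-frame filopodia counts
#'
#' @param object a \code{\link{count_filopodia}} result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.filo_counts <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame,
                                       y = .data$n_filopodia)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "frame", y = "filopodia in existence")
}

#' Plot track length histories
#'
#' Path length over time for every track, one line per filopodium
#' identity.
#'
#' @param tracks a track table from \code{\link{track_movie}}.
#' @return A ggplot.
#' @export
plot_tracks <- function(tracks) {
  long <- tidyr::unnest(tracks[c("track_id", "data")], "data")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$length_um,
                                     group = .data$track_id,
                                     colour = factor(.data$track_id))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::labs(x = "frame", y = "path length (µm)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
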