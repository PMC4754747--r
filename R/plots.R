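# ggplot2 views of the main result types.

#' Scree plot of a mode set
#'
#' @param object A `mode_set` from [pca_modes()].
#' @param top_k How many modes to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mode_set <- function(object, top_k = 20L, ...) {
  k <- min(top_k, length(object$variances))
  df <- tibble(mode = seq_len(k), variance = object$variances[seq_len(k)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$variance)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "PC mode", y = expression(Variance ~ (ring(A)^2)))
}

#' Fitted-versus-observed plot of a functional-mode fit
#'
#' Shows the per-frame functional quantity and the projection along the
#' fitted functional mode, split by training / validation half.
#'
#' @param object A `functional_mode` from [fma()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.functional_mode <- function(object, ...) {
  ggplot2::ggplot(object$projection,
                  ggplot2::aes(x = .data$functional, y = .data$fitted,
                               colour = .data$half)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "functional value", y = "fitted projection",
                  colour = NULL)
}

#' Cluster-size plot of a clustering result
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cluster_result <- function(object, ...) {
  df <- tidy.cluster_result(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "cluster (largest first)", y = "fraction of frames")
}

#' Per-residue RMSF profile plot
#'
#' @param rmsf Tibble from [rmsf_profile()].
#' @return A ggplot, one line per chain.
#' @export
plot_rmsf <- function(rmsf) {
  ggplot2::ggplot(rmsf, ggplot2::aes(x = .data$residue_index, y = .data$rmsf,
                                     colour = .data$chain_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = expression(RMSF ~ (ring(A))),
                  colour = "chain")
}

#' Interface-SASA series plot
#'
#' @param series Tibble from [interface_sasa_series()].
#' @return A ggplot.
#' @export
plot_sasa_series <- function(series) {
  ggplot2::ggplot(series, ggplot2::aes(x = .data$frame_label, y = .data$sasa)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = expression(interface ~ SASA ~ (ring(A)^2)))
}
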