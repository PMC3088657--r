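#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_col geom_vline
#'   labs theme_minimal coord_flip
#' @export
ggplot2::autoplot

#' Plot the decoy score distribution
#'
#' Histogram of the decoy combined scores (sigma); an optional query score
#' is drawn as a vertical line, so its empirical p-value is the mass to the
#' right of the line.
#'
#' @param object a [score_reference].
#' @param S optional query combined score.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot score_reference
#' @export
autoplot.score_reference <- function(object, S = NULL, ...) {
  df <- tibble(sigma = object$sigma)
  p <- ggplot(df, aes(x = .data$sigma)) +
    geom_histogram(bins = 50, fill = "grey55", colour = "white") +
    labs(x = "decoy combined score", y = "decoys",
         title = sprintf("decoy reference (n = %d)", object$n)) +
    theme_minimal()
  if (!is.null(S)) p <- p + geom_vline(xintercept = S, colour = "firebrick")
  p
}

#' Plot the normalized descriptor profile of a scored complex
#'
#' @param object a `score_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot score_result
#' @export
autoplot.score_result <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$descriptor, y = .data$normalized)) +
    geom_col(fill = "steelblue") +
    coord_flip() +
    labs(y = "normalized component (fraction of decoys beaten)", x = NULL,
         title = sprintf("S = %.2f / 7%s", object$S,
                         if (!is.na(object$p)) sprintf(", p = %.3g", object$p)
                         else "")) +
    theme_minimal()
}

#' Plot the p-value distribution of a pipeline run
#'
#' @param object a `ligtrans_run`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ligtrans_run
#' @export
autoplot.ligtrans_run <- function(object, ...) {
  df <- object$report
  ggplot(df, aes(x = .data$p)) +
    geom_histogram(breaks = seq(0, 1, 0.05), fill = "grey55",
                   colour = "white") +
    geom_vline(xintercept = object$config$p_cutoff, colour = "firebrick") +
    labs(x = "empirical p-value", y = "predictions") +
    theme_minimal()
}
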