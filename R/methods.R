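#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Threshold profile of a GMYC fit
#'
#' One row per candidate threshold: position, maximized log-likelihood,
#' entity count and fitted rate parameters.
#'
#' @param x A `gmyc_fit` object.
#' @param ... Unused.
#' @return A tibble `(threshold, logL, K, lambda1, p1, lambda2, p2)`.
#' @export
tidy.gmyc_fit <- function(x, ...) {
  x$profile
}

#' One-row summary of a GMYC fit
#'
#' @param x A `gmyc_fit` object.
#' @param ... Unused.
#' @return A tibble with the ML threshold, entity counts, log-likelihoods,
#'   LRT and confidence ranges.
#' @export
glance.gmyc_fit <- function(x, ...) {
  part <- x$partition
  ent <- part[!duplicated(part$entity), ]
  tibble::tibble(
    threshold = x$threshold,
    K = x$K,
    n_clusters = sum(ent$kind == "cluster"),
    n_singletons = sum(ent$kind == "singleton"),
    logL = x$logL,
    logL_null = x$null$logL,
    statistic = x$lrt$statistic,
    df = x$lrt$df,
    p_value = x$lrt$p_value,
    K_min = x$confidence$K_min,
    K_max = x$confidence$K_max,
    T_min = x$confidence$T_min,
    T_max = x$confidence$T_max
  )
}

#' @export
glance.null_fit <- function(x, ...) {
  tibble::tibble(lambda = x$lambda, p = x$p, logL = x$logL,
                 n_intervals = x$n_intervals)
}

#' Plot a GMYC fit
#'
#' `type = "ltt"` draws the lineage-through-time curve with the ML threshold
#' and its confidence range; `type = "profile"` draws the threshold
#' log-likelihood profile with the 2-log-likelihood support band.
#'
#' @param object A `gmyc_fit` object.
#' @param type `"ltt"` or `"profile"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gmyc_fit <- function(object, type = c("ltt", "profile"), ...) {
  type <- match.arg(type)
  if (type == "ltt") {
    plot_ltt(object$tree, object$threshold) +
      ggplot2::annotate("rect",
                        xmin = object$confidence$T_min,
                        xmax = object$confidence$T_max,
                        ymin = -Inf, ymax = Inf, alpha = 0.1, fill = "red")
  } else {
    cut <- max(object$profile$logL) - object$options$delta
    ggplot2::ggplot(object$profile,
                    ggplot2::aes(x = .data$threshold, y = .data$logL)) +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::geom_hline(yintercept = cut, linetype = "dotted") +
      ggplot2::geom_vline(xintercept = object$threshold,
                          linetype = "dashed", colour = "red") +
      ggplot2::labs(x = "threshold (time before present)",
                    y = "profile log-likelihood") +
      ggplot2::theme_minimal()
  }
}

#' Plot a substitution-saturation series
#'
#' Transitions against TN93 distance for every pair, with the quartile
#' slopes that back the saturation verdict.
#'
#' @param object A tibble from [saturation_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.saturation_series <- function(object, ...) {
  dat <- object[object$defined, ]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$distance, y = .data$transitions)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4) +
    ggplot2::labs(x = "TN93 distance", y = "transitions",
                  subtitle = paste("verdict:", attr(object, "verdict"))) +
    ggplot2::theme_minimal()
}
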