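#' Plot orientation-tuning curves
#'
#' Base-graphics plot of one or more tuning curves over
#' `[-pi/2, pi/2]`.
#'
#' @param x A [tuning_curve()] or list of them.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot_tuning_curves <- function(x, ...) {
  if (inherits(x, "tuning_curve")) x <- list(x)
  th <- x[[1]]$thetas
  vals <- sapply(x, `[[`, "values")
  graphics::matplot(th, vals, type = "l", lty = 1,
                    xlab = expression(theta ~ "(rad)"),
                    ylab = expression(r(theta)), ...)
}

#' Plot resultant-versus-elongation curves
#'
#' Plots |R| against `K = log(kappa)` for each model in a
#' [resultant_curve()] table.
#'
#' @param tab Data frame from [resultant_curve()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot_resultant_curves <- function(tab, ...) {
  models <- unique(tab$model)
  graphics::plot(range(tab$log_kappa), c(0, 1), type = "n",
                 xlab = expression(K == log ~ kappa),
                 ylab = expression(abs(R)), ...)
  for (i in seq_along(models)) {
    d <- tab[tab$model == models[i], ]
    graphics::lines(d$log_kappa, d$resultant, col = i)
  }
  graphics::legend("topleft", legend = models, col = seq_along(models),
                   lty = 1, bty = "n")
}

#' Plot a resultant histogram
#'
#' @param hist An [rhistogram()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot_rhistogram <- function(hist, ...) {
  stopifnot(inherits(hist, "rhistogram"))
  graphics::barplot(hist$counts, names.arg = sprintf("%.1f",
                      utils::head(hist$edges, -1)),
                    xlab = expression(abs(R)), ylab = "count",
                    main = hist$label, ...)
}
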