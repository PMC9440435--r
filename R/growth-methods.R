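#' @method print growth_fit
#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Growth fit: %s model\n", x$model))
  if (!x$converged) {
    cat("  did not converge\n")
    return(invisible(x))
  }
  cat("  coefficients:", paste(sprintf("%s = %.4g", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.4f, P = %.3g, n = %d, window DAS %g-%g\n",
              x$r_squared, x$p_value, nrow(x$data), x$window[1], x$window[2]))
  cat(sprintf("  Timemax = %.1f DAS, biomass at Timemax = %.2f g\n",
              x$timemax, x$biomass_at_timemax))
  invisible(x)
}

#' @method summary growth_fit
#' @export
summary.growth_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.growth_fit")
}

#' @method print summary.growth_fit
#' @export
print.summary.growth_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (f$converged) {
    cat("  residual SD =", format(f$sigma, digits = 4), "\n")
    cat("  residual quartiles:",
        paste(format(stats::quantile(f$residuals, c(0.25, 0.5, 0.75)),
                     digits = 3), collapse = " / "), "\n")
  }
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' Predict biomass from a fitted growth curve
#'
#' @param object a `growth_fit`.
#' @param newdata numeric vector of days (DAS), or a data.frame with a
#'   `das` column; defaults to the fitted days.
#' @param ... unused.
#' @return numeric vector of predicted biomass (g).
#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-convergent fit")
  t <- if (is.null(newdata)) object$data$das
       else if (is.data.frame(newdata)) newdata$das else newdata
  object$curve(t)
}

#' @export
fitted.growth_fit <- function(object, ...) object$fitted.values

#' @export
residuals.growth_fit <- function(object, ...) object$residuals

#' Simulate trajectories from a fitted growth curve
#'
#' Parametric simulation: the fitted curve at the observed days plus
#' Gaussian noise with the fit's residual SD.
#'
#' @param object a converged `growth_fit`.
#' @param nsim number of simulated trajectories.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame with one column per simulation, rows matching the
#'   fitted days.
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-convergent fit")
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu),
                                                         sd = object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted growth curve over its data
#'
#' Base-graphics plot of the observed trajectory, the fitted curve over
#' the whole modelling window (including the forecast segment), and the
#' Timemax / biomass-at-Timemax cross-hairs.
#'
#' @param x a converged `growth_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.growth_fit <- function(x, ...) {
  if (!x$converged) stop("cannot plot a non-convergent fit")
  grid <- seq(x$window[1], x$window[2], by = 0.1)
  yy <- x$curve(grid)
  graphics::plot(x$data$das, x$data$biomass, xlab = "DAS",
                 ylab = "biomass (g)", xlim = range(grid),
                 ylim = range(c(yy, x$data$biomass)),
                 main = sprintf("%s growth model", x$model), ...)
  graphics::lines(grid, yy, col = "steelblue", lwd = 2)
  graphics::abline(v = x$timemax, lty = 2, col = "grey40")
  graphics::abline(h = x$biomass_at_timemax, lty = 2, col = "grey40")
  invisible(x)
}

#' @method print growth_fit_list
#' @export
print.growth_fit_list <- function(x, ...) {
  cat("Growth model suite (", length(x), " fits)\n", sep = "")
  for (m in names(x)) {
    f <- x[[m]]
    if (!f$converged) cat(sprintf("  %-13s did not converge\n", m))
    else cat(sprintf("  %-13s R^2 = %6.4f  P = %8.3g  Timemax = %.1f\n",
                     m, f$r_squared, f$p_value, f$timemax))
  }
  invisible(x)
}

#' @method print tolerance_indices
#' @export
print.tolerance_indices <- function(x, ...) {
  cat("Stress-tolerance indices (WD38 relative to WW38)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
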