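#' @export
print.phenodrift_fit <- function(x, ...) {
  cat(sprintf("Tolerance-dynamics fit, variant %s (%s scenario)\n",
              x$variant, x$scenario))
  cat(sprintf("  fixed: r_c = %g /h, F = %g mM; %d observations\n",
              x$r_c, x$F, x$n_obs))
  if (length(x$free)) {
    est <- x$estimates[x$free]
    se <- x$se[x$free]
    for (p in x$free) {
      cat(sprintf("  %-5s = %.4g (SE %.3g)\n", p, est[[p]], se[[p]]))
    }
  } else {
    cat("  no free parameters (growth-only model)\n")
  }
  cat(sprintf("  logLik = %.3f, pseudo-R2 = %.4f\n", x$logLik, x$pseudo_r2))
  if (!isTRUE(x$convergence$hessian_ok)) {
    cat("  note: Hessian not positive definite; standard errors undefined\n")
  }
  invisible(x)
}

#' @export
summary.phenodrift_fit <- function(object, ...) {
  tab <- if (length(object$free)) {
    data.frame(parameter = object$free,
               estimate = unname(object$estimates[object$free]),
               se = unname(object$se[object$free]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(parameter = character(0), estimate = numeric(0),
               se = numeric(0))
  }
  structure(list(variant = object$variant, scenario = object$scenario,
                 coefficients = tab, logLik = object$logLik,
                 pseudo_r2 = object$pseudo_r2, n_obs = object$n_obs,
                 convergence = object$convergence),
            class = "summary.phenodrift_fit")
}

#' @export
print.summary.phenodrift_fit <- function(x, ...) {
  cat(sprintf("Variant %s (%s): logLik %.3f, pseudo-R2 %.4f, n = %d\n",
              x$variant, x$scenario, x$logLik, x$pseudo_r2, x$n_obs))
  if (nrow(x$coefficients)) print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' @export
coef.phenodrift_fit <- function(object, ...) {
  object$estimates[object$free]
}

#' @export
logLik.phenodrift_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$free), nobs = object$n_obs,
            class = "logLik")
}

#' @export
vcov.phenodrift_fit <- function(object, ...) {
  k <- length(object$free)
  V <- diag(object$se^2, k, k)
  dimnames(V) <- list(object$free, object$free)
  V
}

#' @export
confint.phenodrift_fit <- function(object, parm, level = 0.95, ...) {
  est <- coef(object)
  se <- object$se[names(est)]
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(est - z * se, est + z * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predicted cumulative distributions from a fitted model
#'
#' Re-solves the fitted dynamics and returns the model's cumulative CFU/mL
#' at the data's timepoints and plate levels (the quantities that entered
#' the likelihood).
#'
#' @param object A `"phenodrift_fit"`.
#' @param ... Unused.
#' @return Data frame with `time_h`, `tolerance_mM`, `observed`,
#'   `predicted`.
#' @export
predict.phenodrift_fit <- function(object, ...) {
  # observed/predicted vectors are stored level-major (all times per level)
  grid <- expand.grid(time_h = object$times, tolerance_mM = object$levels)
  data.frame(time_h = grid$time_h, tolerance_mM = grid$tolerance_mM,
             observed = object$observed, predicted = object$predicted)
}

#' @export
residuals.phenodrift_fit <- function(object, ...) {
  to <- asinh(object$observed)
  tp <- asinh(object$predicted)
  if (object$likelihood == "regression") {
    stats::residuals(stats::lm(to ~ tp))
  } else {
    to - tp
  }
}

#' Plot a fitted model against the data
#'
#' Cumulative tolerance distributions by timepoint: observed counts as
#' points, model predictions as lines, log10 y-axis.
#'
#' @param x A `"phenodrift_fit"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.phenodrift_fit <- function(x, ...) {
  pr <- predict(x)
  obs <- matrix(pr$observed, nrow = length(x$times), byrow = FALSE)
  obs <- t(obs)
  pred <- t(matrix(pr$predicted, nrow = length(x$times)))
  floor1 <- function(m) pmax(m, 1)
  graphics::matplot(x$levels, floor1(obs), pch = 16, log = "y",
                    col = seq_along(x$times), xlab = "Tolerance (mM)",
                    ylab = "CFU/mL (cumulative)", ...)
  graphics::matlines(x$levels, floor1(pred), lty = 1,
                     col = seq_along(x$times))
  graphics::legend("topright", legend = paste0(x$times, " h"),
                   col = seq_along(x$times), lty = 1, pch = 16, bty = "n")
  invisible(x)
}
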