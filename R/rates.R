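#' Exponential growth or death rate from a CFU time series
#'
#' Viable-count curves are log-linear during balanced growth or first-order
#' killing, so the specific rate is estimated by ordinary least squares of
#' the binary logarithm of CFU/mL against time, with the slope converted to
#' the natural-log scale (multiplied by `ln 2`).  A culture doubling every
#' 3.5 h therefore reports about 0.198 /h.  Zero counts have no logarithm
#' and are excluded with a warning.
#'
#' @param times Sampling times (h), strictly increasing.
#' @param cfu CFU/mL, non-negative, same length.
#' @param window Optional `c(from, to)` time range (h) to restrict the
#'   regression to.
#' @return An object of class `"rate_estimate"`: list with `rate` (1/h,
#'   positive = growth), `se`, `ci95` (half-width of the 95% confidence
#'   interval), `r_squared` and `n`.
#' @examples
#' t <- 0:6
#' exponential_rate(t, 1000 * 2^(t / 3.5))$rate  # ln(2)/3.5 = 0.198
#' @export
exponential_rate <- function(times, cfu, window = NULL) {
  stopifnot(length(times) == length(cfu),
            !is.unsorted(times, strictly = TRUE), all(cfu >= 0))
  if (!is.null(window)) {
    keep <- times >= window[1] & times <= window[2]
    times <- times[keep]; cfu <- cfu[keep]
  }
  if (any(cfu == 0)) {
    warning(sum(cfu == 0), " zero CFU observation(s) excluded from the ",
            "log-linear regression")
    times <- times[cfu > 0]; cfu <- cfu[cfu > 0]
  }
  if (length(cfu) < 3L) stop("need at least 3 positive CFU values")
  y <- log2(cfu)
  fit <- stats::lm(y ~ times)
  slope <- stats::coef(fit)[["times"]]
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  df <- fit$df.residual
  se2 <- sqrt((rss / df) / sum((times - mean(times))^2))
  structure(
    list(rate = slope * log(2),
         se = se2 * log(2),
         ci95 = stats::qt(0.975, df) * se2 * log(2),
         r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
         n = length(cfu)),
    class = "rate_estimate"
  )
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("rate = %.4g +/- %.2g /h (95%% CI half-width), R2 = %.4f, n = %d\n",
              x$rate, x$ci95, x$r_squared, x$n))
  invisible(x)
}

#' Phenotype-independent death coefficient from time-kill curves
#'
#' At formaldehyde concentrations well above the tolerance of essentially
#' the whole population, killing is first-order with rate proportional to
#' concentration.  Each curve's specific death rate (the negative of its
#' [exponential_rate()]) is regressed on the formaldehyde concentration; the
#' slope is the death coefficient alpha (1/h per mM), independent of the
#' dynamic model fits and useful as a cross-check on them.
#'
#' @param data Data frame with columns `time_h`, `cfu_per_ml` and
#'   `formaldehyde_mM`; each concentration contributes one kill curve
#'   (replicates of a concentration should be averaged or stacked
#'   beforehand).
#' @param window Optional time window passed to [exponential_rate()].
#' @return An object of class `"alpha_estimate"`: list with `alpha`
#'   (slope, 1/h/mM), `intercept`, `se`, `ci95`, `per_concentration`
#'   (data frame of death rates) and `n_concentrations`.
#' @export
alpha_from_timekill <- function(data, window = NULL) {
  stopifnot(all(c("time_h", "cfu_per_ml", "formaldehyde_mM") %in% names(data)))
  concs <- sort(unique(data$formaldehyde_mM))
  if (length(concs) < 2L) stop("need kill curves at >= 2 concentrations")
  death <- vapply(concs, function(f) {
    d <- data[data$formaldehyde_mM == f, ]
    d <- d[order(d$time_h), ]
    -exponential_rate(d$time_h, d$cfu_per_ml, window = window)$rate
  }, numeric(1))
  if (any(death < 0)) {
    warning("net growth observed at concentration(s) ",
            paste(concs[death < 0], collapse = ", "),
            " mM; included as negative death rates")
  }
  per_conc <- data.frame(formaldehyde_mM = concs, death_rate = death)
  if (length(concs) == 2L) {
    slope <- diff(death) / diff(concs)
    return(structure(
      list(alpha = slope, intercept = death[1] - slope * concs[1],
           se = NA_real_, ci95 = NA_real_, per_concentration = per_conc,
           n_concentrations = 2L),
      class = "alpha_estimate"))
  }
  fit <- stats::lm(death ~ concs)
  rss <- sum(stats::residuals(fit)^2)
  se <- sqrt((rss / fit$df.residual) / sum((concs - mean(concs))^2))
  structure(
    list(alpha = stats::coef(fit)[["concs"]],
         intercept = stats::coef(fit)[["(Intercept)"]],
         se = se,
         ci95 = stats::qt(0.975, fit$df.residual) * se,
         per_concentration = per_conc,
         n_concentrations = length(concs)),
    class = "alpha_estimate"
  )
}

#' @export
print.alpha_estimate <- function(x, ...) {
  cat(sprintf("alpha = %.4g +/- %.2g /h/mM from %d concentrations\n",
              x$alpha, x$ci95, x$n_concentrations))
  invisible(x)
}
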