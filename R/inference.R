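# Model variants: which of (alpha, b, v, D) are free in each named model.
# Selection variants always carry alpha; regrowth variants never include
# death parameters (no formaldehyde in the medium).
variant_table <- function() {
  v <- list(
    F1  = list(scenario = "selection", free = c("alpha")),
    F2a = list(scenario = "selection", free = c("alpha", "b")),
    F2b = list(scenario = "selection", free = c("alpha", "v")),
    F2c = list(scenario = "selection", free = c("alpha", "D")),
    F3a = list(scenario = "selection", free = c("alpha", "b", "D")),
    F3b = list(scenario = "selection", free = c("alpha", "v", "D")),
    F4  = list(scenario = "selection", free = c("alpha", "b", "v", "D")),
    M0  = list(scenario = "regrowth",  free = character(0)),
    M1a = list(scenario = "regrowth",  free = c("v")),
    M1b = list(scenario = "regrowth",  free = c("D")),
    M2  = list(scenario = "regrowth",  free = c("v", "D")),
    S0  = list(scenario = "regrowth",  free = character(0)),
    S1a = list(scenario = "regrowth",  free = c("v")),
    S1b = list(scenario = "regrowth",  free = c("D")),
    S2  = list(scenario = "regrowth",  free = c("v", "D"))
  )
  v
}

variant_info <- function(variant) {
  tab <- variant_table()
  if (!variant %in% names(tab)) {
    stop("unknown model variant '", variant, "'; see ?fit_tolerance_model")
  }
  c(list(name = variant), tab[[variant]])
}

#' Log-likelihood of model predictions on the asinh scale
#'
#' Plated counts span many orders of magnitude and include zeros, so both
#' observed and predicted cumulative CFU/mL are transformed with the inverse
#' hyperbolic sine, `asinh(x) = log(x + sqrt(1 + x^2))` -- approximately
#' logarithmic for large counts but defined at zero.  The default
#' (`method = "regression"`) log-likelihood is that of an ordinary
#' least-squares linear model of `asinh(observed)` on `asinh(predicted)`
#' with free intercept and slope and maximum-likelihood residual variance,
#' exactly what `logLik(lm(...))` reports.  The alternative
#' (`method = "identity"`) scores identity-line residuals
#' `asinh(observed) - asinh(predicted)` under a zero-mean Gaussian with
#' maximum-likelihood variance; it is offered for sensitivity analysis.
#' In either case the residual variance is floored at 1e-12 so that a
#' perfect fit yields a large finite value rather than +Inf.
#'
#' @param observed,predicted Paired non-negative values (cumulative CFU/mL
#'   at matching (time, level) coordinates), length >= 3.
#' @param method `"regression"` (default) or `"identity"`.
#' @return Scalar log-likelihood (higher is better).
#' @export
asinh_loglik <- function(observed, predicted,
                         method = c("regression", "identity")) {
  method <- match.arg(method)
  stopifnot(length(observed) == length(predicted), length(observed) >= 3L)
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("observed and predicted must be finite")
  }
  to <- asinh(observed)
  tp <- asinh(predicted)
  n <- length(to)
  if (method == "regression") {
    fit <- stats::lm(to ~ tp)
    rss <- sum(stats::residuals(fit)^2)
  } else {
    rss <- sum((to - tp)^2)
  }
  sigma2 <- max(rss / n, 1e-12)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

#' Pseudo-R-squared of model predictions
#'
#' Coefficient of determination of the same asinh-scale ordinary
#' least-squares regression of observed on predicted counts that defines
#' the default log-likelihood (see [asinh_loglik()]).
#'
#' @inheritParams asinh_loglik
#' @return Scalar in `[0, 1]`, or `NA` (with a warning) when the observed
#'   values are constant on the asinh scale.
#' @export
pseudo_r2 <- function(observed, predicted) {
  to <- asinh(observed)
  tp <- asinh(predicted)
  if (stats::var(to) == 0) {
    warning("observed values are constant; pseudo-R2 undefined")
    return(NA_real_)
  }
  res <- stats::residuals(stats::lm(to ~ tp))
  1 - sum(res^2) / sum((to - mean(to))^2)
}

# ---- parameter transforms: optimize on an unconstrained scale ------------
# alpha, D > 0 via log; b in (0,1) via logit; v unconstrained.
par_to_theta <- function(par, free) {
  vapply(free, function(p) switch(p,
    alpha = log(par[["alpha"]]),
    D     = log(par[["D"]]),
    b     = stats::qlogis(min(max(par[["b"]], 1e-6), 1 - 1e-6)),
    v     = par[["v"]]), numeric(1))
}

theta_to_par <- function(theta, free, fixed) {
  par <- fixed
  theta <- unname(theta)
  for (i in seq_along(free)) {
    par[[free[i]]] <- switch(free[i],
      alpha = exp(theta[i]),
      D     = exp(theta[i]),
      b     = stats::plogis(theta[i]),
      v     = theta[i])
  }
  par
}

# |d(natural)/d(theta)| for delta-method standard errors
theta_jacobian <- function(par, free) {
  vapply(free, function(p) switch(p,
    alpha = par[["alpha"]],
    D     = par[["D"]],
    b     = par[["b"]] * (1 - par[["b"]]),
    v     = 1), numeric(1))
}

# coarse multi-start grid on the natural scale
start_grid <- function(free) {
  values <- list(alpha = c(0.05, 0.15, 0.45),
                 b     = c(0.2, 0.5, 0.8),
                 D     = c(0.005, 0.02, 0.08),
                 v     = c(-0.05, 0.02, 0.2))
  do.call(expand.grid, values[free])
}

# central-difference Hessian with per-coordinate step 1e-4 * max(|theta|, 1)
fd_hessian <- function(fn, theta) {
  k <- length(theta)
  h <- 1e-4 * pmax(abs(theta), 1)
  H <- matrix(NA_real_, k, k)
  f0 <- fn(theta)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    for (j in i:k) {
      ej <- replace(numeric(k), j, h[j])
      if (i == j) {
        H[i, i] <- (fn(theta + ei) - 2 * f0 + fn(theta - ei)) / h[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (fn(theta + ei + ej) - fn(theta + ei - ej) -
           fn(theta - ei + ej) + fn(theta - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Fit the tolerance-dynamics model to a prepared series by maximum likelihood
#'
#' Fits one model variant (a subset of the parameters alpha, b, D, v free,
#' the rest pinned at zero) to a replicate-averaged cumulative
#' tolerance-distribution series.  The first timepoint's distribution is
#' interpolated to the model grid by monotone cubic spline and used as the
#' initial condition; the model is solved at the remaining timepoints,
#' binned back to the data's plate levels in cumulative form, and scored
#' against all observations with [asinh_loglik()].  Optimization is
#' Nelder-Mead on transformed parameters (log for alpha and D, logit for b)
#' from a deterministic coarse multi-start grid; standard errors come from
#' the finite-difference Hessian of the negative log-likelihood at the
#' optimum, delta-method-mapped to the natural scale.
#'
#' Selection-scenario variants: `F1` (alpha), `F2a` (+b), `F2b` (+v),
#' `F2c` (+D), `F3a` (alpha, b, D), `F3b` (alpha, v, D), `F4` (all four).
#' Regrowth variants (no death): `M0`/`S0` (growth only), `M1a`/`S1a` (v),
#' `M1b`/`S1b` (D), `M2`/`S2` (v and D).
#'
#' @param data Prepared series (see [prepare_series()]): replicate-averaged,
#'   monotone cumulative CFU/mL in the canonical long format, one condition.
#' @param variant Variant name (see Details).
#' @param r_c Growth rate (1/h), fixed from independent growth-curve
#'   regressions (see [substrate_growth_rate()]).
#' @param F Medium formaldehyde (mM); defaults to 4 for selection variants,
#'   0 for regrowth variants.
#' @param dx,L Fitting grid (mM); `L` defaults to 2 mM above the highest
#'   plate level.
#' @param likelihood Passed to [asinh_loglik()].
#' @param n_starts Number of Nelder-Mead starts, taken from the best points
#'   of the coarse start grid.
#' @param start Optional named list/vector of natural-scale starting values
#'   for the free parameters (prepended to the multi-start list; used for
#'   warm starts in the stepwise procedure).
#' @param init Optional initial density on the fitting grid.  By default the
#'   initial condition is reconstructed from the first timepoint's coarse
#'   cumulative distribution by monotone spline
#'   ([interpolate_initial_condition()]), as in the standard pipeline;
#'   supplying `init` bypasses that reconstruction (useful for
#'   self-consistency tests where the generating density is known).
#' @param rtol Solver relative tolerance used during fitting.
#' @param control Passed to [stats::optim()] (Nelder-Mead).
#' @return An object of class `"phenodrift_fit"`.
#' @seealso [lr_test()], [select_model()]
#' @export
fit_tolerance_model <- function(data, variant, r_c,
                                F = NULL, dx = 0.01, L = NULL,
                                likelihood = c("regression", "identity"),
                                n_starts = 2L, start = NULL, init = NULL,
                                rtol = 1e-8,
                                control = list(maxit = 500)) {
  likelihood <- match.arg(likelihood)
  info <- variant_info(variant)
  if (is.null(F)) F <- if (info$scenario == "selection") 4 else 0
  data <- validate_series(data)
  if (length(unique(data$replicate)) != 1L) {
    stop("fit expects a replicate-averaged series; see prepare_series()")
  }

  levels <- sort(unique(data$tolerance_mM))
  times <- sort(unique(data$time_h))
  if (length(times) < 2L) stop("need at least two timepoints")
  if (is.null(L)) L <- max(levels) + 2
  grid <- tolerance_grid(L, dx)

  obs_mat <- matrix(NA_real_, length(times), length(levels))
  for (i in seq_along(times)) {
    block <- data[data$time_h == times[i], ]
    block <- block[order(block$tolerance_mM), ]
    if (!identical(block$tolerance_mM, levels)) {
      stop("all timepoints must share the same tolerance levels")
    }
    obs_mat[i, ] <- block$cfu_per_ml
  }
  if (is.null(init)) {
    init_counts <- cummin(obs_mat[1, ])
    init <- interpolate_initial_condition(init_counts, levels, grid)
  } else {
    check_density(init, grid)
  }
  times_model <- times - times[1]
  observed <- as.vector(obs_mat)

  predict_fun <- function(par) {
    params <- model_parameters(r_c = r_c, alpha = par[["alpha"]],
                               b = par[["b"]], D = par[["D"]],
                               v = par[["v"]], F = F)
    sim <- simulate_dynamics(init, params, times_model, grid, rtol = rtol)
    pred <- vapply(seq_along(times_model), function(i) {
      bin_to_data_resolution(sim$densities[i, ], grid, levels)
    }, numeric(length(levels)))
    as.vector(t(pred))
  }

  fixed <- list(alpha = 0, b = 0, D = 0, v = 0)
  free <- info$free
  objective <- function(theta) {
    par <- theta_to_par(theta, free, fixed)
    ll <- tryCatch(asinh_loglik(observed, predict_fun(par), likelihood),
                   error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  if (length(free) == 0L) {
    par_hat <- fixed
    ll <- asinh_loglik(observed, predict_fun(par_hat), likelihood)
    opt <- list(convergence = 0L, counts = c(0, 0))
    se <- numeric(0)
    hessian_ok <- TRUE
    theta_hat <- numeric(0)
  } else {
    starts <- start_grid(free)
    theta_starts <- t(apply(starts, 1, function(row) {
      par_to_theta(as.list(row), free)
    }))
    if (length(free) == 1L) theta_starts <- matrix(theta_starts, ncol = 1L)
    if (!is.null(start)) {
      start <- as.list(start)
      theta_starts <- rbind(par_to_theta(start, free), theta_starts)
    }
    screen <- apply(theta_starts, 1, objective)
    keep <- order(screen)[seq_len(min(n_starts, nrow(theta_starts)))]
    fits <- lapply(keep, function(k) {
      if (length(free) == 1L) {
        stats::optim(theta_starts[k, ], objective, method = "Brent",
                     lower = theta_starts[k, ] - 8,
                     upper = theta_starts[k, ] + 8)
      } else {
        stats::optim(theta_starts[k, ], objective, method = "Nelder-Mead",
                     control = control)
      }
    })
    best <- which.min(vapply(fits, `[[`, numeric(1), "value"))
    opt <- fits[[best]]
    if (!is.finite(opt$value) || opt$value >= 1e10) {
      stop("all optimization starts failed to produce a finite likelihood")
    }
    theta_hat <- opt$par
    par_hat <- theta_to_par(theta_hat, free, fixed)
    ll <- -opt$value
    H <- fd_hessian(objective, theta_hat)
    cov_theta <- tryCatch(solve(H), error = function(e) NULL)
    hessian_ok <- !is.null(cov_theta) && all(diag(cov_theta) > 0)
    se <- if (hessian_ok) {
      sqrt(diag(as.matrix(cov_theta))) * theta_jacobian(par_hat, free)
    } else rep(NA_real_, length(free))
    names(se) <- free
  }

  predicted <- predict_fun(par_hat)
  structure(
    list(variant = variant, scenario = info$scenario, free = free,
         estimates = unlist(par_hat), se = se,
         logLik = ll, pseudo_r2 = pseudo_r2(observed, predicted),
         n_obs = length(observed),
         convergence = list(code = opt$convergence, counts = opt$counts,
                            hessian_ok = hessian_ok),
         r_c = r_c, F = F, grid = grid, likelihood = likelihood,
         levels = levels, times = times, observed = observed,
         predicted = predicted, init = init, data = data,
         theta = theta_hat),
    class = "phenodrift_fit"
  )
}

#' Likelihood-ratio test between two nested fits
#'
#' `LR = -2 (LL0 - LL1)` with `LL0` the log-likelihood of the reduced model
#' and `LL1` that of the expanded model; the p-value is the chi-squared
#' upper tail with degrees of freedom equal to the difference in the number
#' of free parameters.  A (small) negative LR indicates an optimizer failure
#' on the larger model and is reported as-is, not clamped.
#'
#' @param null_fit,alt_fit `"phenodrift_fit"` objects; the null variant's
#'   free parameters must be a subset of the alternative's.
#' @return An object of class `"phenodrift_lrt"`: list with `null_variant`,
#'   `alt_variant`, `LR`, `df` and `p`.
#' @examples
#' # LL0 = -10, LL1 = -5, df = 1  ->  LR = 10, p ~ 0.00157
#' @export
lr_test <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "phenodrift_fit"),
            inherits(alt_fit, "phenodrift_fit"))
  if (!all(null_fit$free %in% alt_fit$free) ||
      length(alt_fit$free) <= length(null_fit$free)) {
    stop("models are not nested (null free parameters must be a strict ",
         "subset of the alternative's)")
  }
  LR <- -2 * (null_fit$logLik - alt_fit$logLik)
  df <- length(alt_fit$free) - length(null_fit$free)
  p <- stats::pchisq(LR, df = df, lower.tail = FALSE)
  structure(list(null_variant = null_fit$variant,
                 alt_variant = alt_fit$variant,
                 LR = LR, df = df, p = p),
            class = "phenodrift_lrt")
}

#' @export
print.phenodrift_lrt <- function(x, ...) {
  cat(sprintf("LRT %s vs %s: LR = %.3f, df = %d, p = %.3g\n",
              x$alt_variant, x$null_variant, x$LR, x$df, x$p))
  invisible(x)
}

# candidate one-parameter expansions of a free set within one scenario,
# named with the conventional labels (M* for methanol, S* for succinate)
expansion_candidates <- function(free, scenario, prefix = NULL) {
  tab <- variant_table()
  names(tab)[vapply(names(tab), function(nm) {
    entry <- tab[[nm]]
    ok <- entry$scenario == scenario &&
      all(free %in% entry$free) && length(entry$free) == length(free) + 1L
    if (ok && scenario == "regrowth" && !is.null(prefix)) {
      ok <- startsWith(nm, prefix)
    }
    ok
  }, logical(1))]
}

#' Forward stepwise model selection by likelihood-ratio test
#'
#' Starting from the scenario's minimal model (`F1`, death only, for
#' selection; `M0`/`S0`, growth only, for regrowth), fits every
#' one-parameter expansion at each step, keeps the expansion with the
#' highest likelihood if its likelihood-ratio test against the current model
#' is significant at `alpha_level`, and repeats until no expansion is
#' accepted or the lattice is exhausted.  Expansion fits are warm-started
#' from the current model's estimates.
#'
#' @inheritParams fit_tolerance_model
#' @param scenario `"selection"` or `"regrowth"`.
#' @param substrate For regrowth, `"methanol"` or `"succinate"` (controls
#'   the variant labels `M*` vs `S*`); taken from the data if present.
#' @param alpha_level Significance threshold for accepting an expansion.
#' @param ... Passed to [fit_tolerance_model()].
#' @return An object of class `"phenodrift_selection"`: list with
#'   `selected` (the final `"phenodrift_fit"`), `trace` (data frame of
#'   every fit and test), and `fits` (all fitted objects by variant name).
#' @export
select_model <- function(data, scenario = c("selection", "regrowth"),
                         r_c, F = NULL, substrate = NULL,
                         alpha_level = 0.05, ...) {
  scenario <- match.arg(scenario)
  if (is.null(substrate)) {
    substrate <- if (!is.null(data$substrate)) data$substrate[1] else "methanol"
  }
  prefix <- if (scenario == "regrowth") {
    if (substrate == "succinate") "S" else "M"
  } else NULL
  base_variant <- if (scenario == "selection") "F1"
                  else if (prefix == "S") "S0" else "M0"
  current <- fit_tolerance_model(data, base_variant, r_c = r_c, F = F, ...)
  fits <- stats::setNames(list(current), base_variant)
  trace <- data.frame(variant = base_variant, null = NA_character_,
                      logLik = current$logLik, LR = NA_real_,
                      df = NA_integer_, p = NA_real_, accepted = TRUE,
                      stringsAsFactors = FALSE)
  repeat {
    cands <- expansion_candidates(current$free, scenario, prefix)
    if (!length(cands)) break
    cand_fits <- list()
    for (nm in cands) {
      new_par <- setdiff(variant_info(nm)$free, current$free)
      warm <- as.list(current$estimates[c("alpha", "b", "D", "v")])
      warm <- warm[variant_info(nm)$free]
      # seed the added parameter away from its boundary
      warm[[new_par]] <- switch(new_par, alpha = 0.1, b = 0.5,
                                D = 0.01, v = 0.02)
      f <- tryCatch(
        fit_tolerance_model(data, nm, r_c = r_c, F = F, start = warm, ...),
        error = function(e) e)
      if (inherits(f, "error")) {
        trace <- rbind(trace, data.frame(
          variant = nm, null = current$variant, logLik = NA_real_,
          LR = NA_real_, df = NA_integer_, p = NA_real_, accepted = FALSE,
          stringsAsFactors = FALSE))
        next
      }
      cand_fits[[nm]] <- f
    }
    if (!length(cand_fits)) break
    lls <- vapply(cand_fits, `[[`, numeric(1), "logLik")
    best_nm <- names(which.max(lls))
    best <- cand_fits[[best_nm]]
    test <- lr_test(current, best)
    for (nm in names(cand_fits)) {
      t_nm <- lr_test(current, cand_fits[[nm]])
      trace <- rbind(trace, data.frame(
        variant = nm, null = current$variant,
        logLik = cand_fits[[nm]]$logLik, LR = t_nm$LR, df = t_nm$df,
        p = t_nm$p, accepted = nm == best_nm && test$p < alpha_level,
        stringsAsFactors = FALSE))
    }
    fits[names(cand_fits)] <- cand_fits
    if (test$p < alpha_level) current <- best else break
  }
  structure(list(selected = current, trace = trace, fits = fits),
            class = "phenodrift_selection")
}

#' @export
print.phenodrift_selection <- function(x, ...) {
  cat(sprintf("Stepwise model selection: %s selected (free: %s)\n",
              x$selected$variant,
              if (length(x$selected$free)) paste(x$selected$free,
                                                 collapse = ", ")
              else "none"))
  print(x$trace, row.names = FALSE, digits = 4)
  invisible(x)
}
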