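#' Describe a plating experiment
#'
#' Collects the design constants of a tolerance-distribution experiment: the
#' selective environment, sampling times, the tolerance levels assayed on
#' selective plates, and the serial-dilution plating scheme whose counting
#' floor (about 34 CFU/mL per replicate, one colony per 30 uL plated)
#' produces the data's detection limit.
#'
#' The defaults reproduce the standard experiments: cultures inoculated at
#' ~3e6 CFU/mL and sampled every 4 hours starting from the 2-hour sample
#' (the first point after the stationary-to-exponential transition, used as
#' the model's initial condition), plated as three 10-uL spots from a
#' 10-fold dilution series.  Selection uses 4 mM formaldehyde in the medium
#' and 1-mM plate levels from 0 to 10; regrowth uses formaldehyde-free
#' medium and 2-mM plate levels from 0 to 12.
#'
#' @param condition `"selection"` or `"regrowth"`.
#' @param substrate `"methanol"` or `"succinate"`.
#' @param F Medium formaldehyde (mM); defaults to 4 for selection, 0 for
#'   regrowth.
#' @param timepoints Sampling times (h on the experiment clock).
#' @param plate_levels Formaldehyde concentrations of the selective plates
#'   (mM).
#' @param replicates Number of biological replicates.
#' @param N_total Initial population (CFU/mL).
#' @param plated_volume Volume per spot (mL); three spots are pooled per
#'   replicate when counting.
#' @param dilution_factors Serial-dilution factors available.
#' @param detection_limit Smallest detectable abundance (CFU/mL) per
#'   replicate, for reference.
#' @param L Upper boundary of the tolerance grid (mM), above the highest
#'   plate level.
#' @param dx Grid step for the generating simulation (mM).
#' @return An object of class `"experiment_design"` (a list).
#' @export
experiment_design <- function(condition = c("selection", "regrowth"),
                              substrate = c("methanol", "succinate"),
                              F = NULL,
                              timepoints = c(2, 6, 10, 14, 18, 22),
                              plate_levels = NULL,
                              replicates = 3L,
                              N_total = 3e6,
                              plated_volume = 0.010,
                              dilution_factors = 10^-(0:6),
                              detection_limit = 34,
                              L = NULL,
                              dx = 0.01) {
  condition <- match.arg(condition)
  substrate <- match.arg(substrate)
  if (is.null(F)) F <- if (condition == "selection") 4 else 0
  if (is.null(plate_levels)) {
    plate_levels <- if (condition == "selection") seq(0, 10, by = 1)
                    else seq(0, 12, by = 2)
  }
  stopifnot(plate_levels[1] == 0, !is.unsorted(plate_levels, strictly = TRUE),
            replicates >= 1L, N_total > 0)
  if (is.null(L)) L <- max(plate_levels) + 2
  structure(
    list(condition = condition, substrate = substrate, F = F,
         timepoints = timepoints, plate_levels = plate_levels,
         replicates = as.integer(replicates), N_total = N_total,
         plated_volume = plated_volume, dilution_factors = dilution_factors,
         detection_limit = detection_limit, L = L, dx = dx),
    class = "experiment_design"
  )
}

#' Growth rate appropriate to a design's substrate
#'
#' 0.195 /h on methanol and 0.267 /h on succinate, the regression estimates
#' from naive growth curves under the standard culture conditions.
#'
#' @param substrate `"methanol"` or `"succinate"`.
#' @return Per-capita growth rate (1/h).
#' @export
substrate_growth_rate <- function(substrate = c("methanol", "succinate")) {
  switch(match.arg(substrate), methanol = 0.195, succinate = 0.267)
}

#' Construct an exponentially decreasing initial tolerance distribution
#'
#' Naive populations carry tolerance frequencies that decline roughly
#' exponentially with tolerance level: the cumulative frequency of cells
#' tolerating at least `x` mM is `10^(log10_slope * x)` (about 1e-4 at 4 mM
#' for the default slope of -1).  Populations that have already been through
#' selection are modelled with a tolerant shoulder: the cumulative frequency
#' stays at 1 up to `shoulder` mM and declines beyond it.  Frequencies below
#' the plating detection limit are truncated to zero.  The cumulative curve
#' is differenced on the fine grid to give a phenotype density summing to
#' `N_total`.
#'
#' @param log10_slope Slope of log10 cumulative frequency per mM (< 0).
#' @param N_total Total population (CFU/mL).
#' @param grid A [tolerance_grid()].
#' @param shoulder Tolerance (mM) below which the cumulative frequency is 1.
#' @param detection_freq Frequency below which subpopulations are treated as
#'   absent (default 1.65e-7, one cell per 30 uL of a 2e8 CFU/mL culture).
#' @return Density vector on `grid` summing to `N_total`.
#' @examples
#' g <- tolerance_grid(12, 0.1)
#' den <- make_initial_distribution(-1, 2e6, g)
#' sum(den)                                    # 2e6
#' density_to_cumulative(den)[g$x == 4]        # ~200: frequency 1e-4
#' @export
make_initial_distribution <- function(log10_slope, N_total, grid,
                                      shoulder = 0,
                                      detection_freq = 1.65e-7) {
  stopifnot(is.finite(log10_slope), is.finite(N_total), N_total > 0,
            shoulder >= 0)
  if (log10_slope >= 0) stop("'log10_slope' must be negative")
  check <- inherits(grid, "tolerance_grid")
  if (!check) stop("'grid' must be a tolerance_grid")
  cumfreq <- 10^(log10_slope * pmax(grid$x - shoulder, 0))
  cumfreq[cumfreq < detection_freq] <- 0
  cum <- cumfreq * N_total
  c(-diff(cum), cum[length(cum)])
}

#' Simulate the noise-free observable of an experiment
#'
#' Runs the forward dynamics from `init` under `params`, on the simulation
#' clock starting at the design's first timepoint, and bins the result to
#' the design's plate levels in cumulative form: the expected CFU/mL a
#' perfect (noise-free) plating assay would measure.
#'
#' @param params A [model_parameters()] object (its `F` should match the
#'   design's).
#' @param design An [experiment_design()].
#' @param init Initial density on the design's grid; defaults to
#'   [make_initial_distribution()] with slope -1 (naive population) for
#'   selection designs and a 4-mM tolerant shoulder for regrowth designs.
#' @param ... Passed to [simulate_dynamics()].
#' @return Long-format series (replicate `"true"`) of noise-free cumulative
#'   CFU/mL at every (timepoint, plate level).
#' @export
simulate_experiment <- function(params, design, init = NULL, ...) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- tolerance_grid(design$L, design$dx)
  if (is.null(init)) {
    shoulder <- if (design$condition == "selection") 0 else 4
    init <- make_initial_distribution(-1, design$N_total, grid,
                                      shoulder = shoulder)
  }
  times_model <- design$timepoints - design$timepoints[1]
  sim <- simulate_dynamics(init, params, times_model, grid, ...)
  out <- expand.grid(tolerance_mM = design$plate_levels,
                     time_h = design$timepoints)
  out$cfu_per_ml <- as.vector(vapply(seq_along(sim$times), function(i) {
    bin_to_data_resolution(sim$densities[i, ], grid, design$plate_levels)
  }, numeric(length(design$plate_levels))))
  data.frame(condition = design$condition, substrate = design$substrate,
             replicate = "true", time_h = out$time_h,
             tolerance_mM = out$tolerance_mM, cfu_per_ml = out$cfu_per_ml,
             stringsAsFactors = FALSE)
}

# internal: pick the dilution whose pooled 30-uL spot count is countable
pick_dilution <- function(cfu, dilution_factors, pooled_volume) {
  m <- cfu * pooled_volume * dilution_factors
  ok <- which(m <= 300)
  if (length(ok)) dilution_factors[ok[1]] else min(dilution_factors)
}

#' Observe a noise-free series through the plating process
#'
#' Emulates serial-dilution spot plating: for each (time, level, replicate)
#' the least-dilute countable dilution is chosen (expected pooled count of
#' at most 300 colonies over three 10-uL spots), a Poisson colony count is
#' drawn at that dilution, and converted back to CFU/mL.  Counts of zero
#' report 0 CFU/mL, so the ~33 CFU/mL detection floor emerges naturally
#' from the counting process rather than being imposed.
#'
#' @param true_series Output of [simulate_experiment()] (replicate `"true"`).
#' @param design The [experiment_design()].
#' @param seed Integer seed; identical seeds reproduce the dataset exactly.
#' @return Long-format series with `design$replicates` noisy replicates.
#' @export
observe_plating <- function(true_series, design, seed = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  if (!is.null(seed)) set.seed(seed)
  pooled <- 3 * design$plated_volume
  reps <- seq_len(design$replicates)
  out <- do.call(rbind, lapply(reps, function(r) {
    d <- true_series
    d$replicate <- sprintf("rep%d", r)
    d
  }))
  dil <- vapply(out$cfu_per_ml, pick_dilution,
                numeric(1), dilution_factors = design$dilution_factors,
                pooled_volume = pooled)
  counts <- stats::rpois(nrow(out), out$cfu_per_ml * pooled * dil)
  out$cfu_per_ml <- counts / (pooled * dil)
  rownames(out) <- NULL
  validate_series(out)
}

#' Generate a complete synthetic plating dataset
#'
#' Composes [make_initial_distribution()], [simulate_experiment()] and
#' [observe_plating()]: the forward dynamics under `params` observed through
#' the Poisson plating process.
#'
#' @param params A [model_parameters()].
#' @param design An [experiment_design()].
#' @param seed Integer seed for the observation noise.
#' @param init Optional initial density (defaults as in
#'   [simulate_experiment()]).
#' @param ... Passed to [simulate_dynamics()].
#' @return An object of class `"synthetic_dataset"`: list with `design`,
#'   `params`, `true_series`, `observed_series` and `seed`.
#' @export
make_synthetic_dataset <- function(params, design, seed, init = NULL, ...) {
  true_series <- simulate_experiment(params, design, init = init, ...)
  observed <- observe_plating(true_series, design, seed = seed)
  structure(
    list(design = design, params = params, true_series = true_series,
         observed_series = observed, seed = seed),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "Synthetic %s dataset (%s, F = %g mM): %d timepoints x %d levels x %d replicates, seed %s\n",
    x$design$condition, x$design$substrate, x$design$F,
    length(x$design$timepoints), length(x$design$plate_levels),
    x$design$replicates, format(x$seed)))
  invisible(x)
}

#' Quantify parameter recovery over repeated synthetic experiments
#'
#' Generates `n_datasets` synthetic datasets under `true_params`, pushes
#' each through the full pipeline (detection-limit extension, replicate
#' averaging, spline initial condition, maximum-likelihood fit), and
#' tabulates recovery: per-parameter estimates, relative errors, Wald
#' 95%-interval coverage of the truth, and (optionally) stepwise
#' model-selection outcomes.
#'
#' @param true_params Generating [model_parameters()].
#' @param design [experiment_design()] under which data are generated.
#' @param n_datasets Number of synthetic datasets.
#' @param seed Master seed; dataset `i` uses `seed + i`.
#' @param variant Variant fitted to each dataset (see
#'   [fit_tolerance_model()]); ignored when `select = TRUE`.
#' @param select If `TRUE`, run [select_model()] on each dataset instead of
#'   fitting a single variant, and record the chosen free-parameter set.
#' @param fit_dx,fit_L Grid used for fitting (may be coarser than the
#'   generating grid).
#' @param ... Further arguments to [fit_tolerance_model()] /
#'   [select_model()].
#' @return An object of class `"recovery_study"`: list with `estimates`
#'   (data frame, one row per dataset), `true_params`, `summary` (bias,
#'   median absolute relative error, coverage per free parameter), and
#'   `selected` (character vector of selected variants, if `select`).
#' @export
recovery_study <- function(true_params, design, n_datasets, seed,
                           variant = "F3a", select = FALSE,
                           fit_dx = 0.1, fit_L = design$L, ...) {
  stopifnot(n_datasets >= 1)
  rows <- vector("list", n_datasets)
  selected <- character(n_datasets)
  r_c <- substrate_growth_rate(design$substrate)
  for (i in seq_len(n_datasets)) {
    ds <- make_synthetic_dataset(true_params, design, seed = seed + i)
    prepared <- prepare_series(ds$observed_series)
    res <- tryCatch({
      if (select) {
        sel <- select_model(prepared, scenario = design$condition,
                            r_c = r_c, F = design$F,
                            dx = fit_dx, L = fit_L, ...)
        selected[i] <- sel$selected$variant
        sel$selected
      } else {
        fit_tolerance_model(prepared, variant = variant, r_c = r_c,
                            F = design$F, dx = fit_dx, L = fit_L, ...)
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- NULL
      selected[i] <- NA_character_
      warning(sprintf("dataset %d failed: %s", i, conditionMessage(res)))
      next
    }
    est <- coef(res)
    se <- res$se
    rows[[i]] <- data.frame(dataset = i, parameter = names(est),
                            estimate = unname(est),
                            se = unname(se[names(est)]),
                            stringsAsFactors = FALSE)
  }
  estimates <- do.call(rbind, rows)
  truth <- unlist(true_params[c("alpha", "b", "D", "v")])
  summary_tab <- NULL
  if (!is.null(estimates) && nrow(estimates)) {
    estimates$truth <- truth[estimates$parameter]
    estimates$rel_error <- with(estimates, (estimate - truth) / truth)
    estimates$covered <- with(estimates,
      is.finite(se) & abs(estimate - truth) <= 1.959964 * se)
    summary_tab <- do.call(rbind, lapply(split(estimates, estimates$parameter),
      function(d) data.frame(
        parameter = d$parameter[1],
        bias = mean(d$estimate - d$truth),
        median_abs_rel_error = stats::median(abs(d$rel_error)),
        coverage = mean(d$covered),
        n = nrow(d))))
    rownames(summary_tab) <- NULL
  }
  structure(
    list(estimates = estimates, true_params = true_params,
         summary = summary_tab,
         selected = if (select) selected else NULL,
         seed = seed, n_datasets = n_datasets),
    class = "recovery_study"
  )
}

#' @export
print.recovery_study <- function(x, ...) {
  cat(sprintf("Parameter-recovery study: %d synthetic datasets (seed %s)\n",
              x$n_datasets, format(x$seed)))
  if (!is.null(x$summary)) print(x$summary, row.names = FALSE)
  if (!is.null(x$selected)) {
    cat("Selected variants:\n")
    print(table(x$selected, useNA = "ifany"))
  }
  invisible(x)
}
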