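#' Model parameters for the structured-population dynamics
#'
#' The population density `N(x, t)` over tolerance `x` evolves by growth at
#' per-capita rate `r_c`, formaldehyde-dependent death at rate
#' `H(x, F) = alpha * (F - b x)` for `x < F` (zero otherwise), phenotypic
#' diffusion with coefficient `D`, and phenotypic advection at rate `v`.
#' With the model's sign convention a positive `v` transports the population
#' toward *lower* tolerance.
#'
#' @param r_c Per-capita growth rate (1/h), substrate-specific; 0.195 for
#'   methanol and 0.267 for succinate under the standard culture conditions.
#' @param alpha Death-rate coefficient (1/h per mM medium formaldehyde).
#' @param b Sensitivity of the death rate to a cell's own tolerance
#'   (mM tolerance per mM formaldehyde, in `[0, 1]`).
#' @param D Phenotypic diffusion coefficient (mM^2/h, tolerance units).
#' @param v Phenotypic advection rate (mM/h); positive values drift the
#'   population toward lower tolerance.
#' @param F Medium formaldehyde concentration (mM); 4 in the standard
#'   selection experiment, 0 during formaldehyde-free regrowth.
#' @return An object of class `"model_parameters"`.
#' @export
model_parameters <- function(r_c, alpha = 0, b = 0, D = 0, v = 0, F = 0) {
  stopifnot(is.finite(r_c), r_c >= 0,
            is.finite(alpha), alpha >= 0,
            is.finite(b), b >= 0, b <= 1,
            is.finite(D), D >= 0,
            is.finite(v),
            is.finite(F), F >= 0)
  structure(list(r_c = r_c, alpha = alpha, b = b, D = D, v = v, F = F),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat(sprintf(
    "Model parameters: r_c = %.4g /h, alpha = %.4g /h/mM, b = %.4g,\n  D = %.4g mM^2/h, v = %.4g mM/h, F = %g mM\n",
    x$r_c, x$alpha, x$b, x$D, x$v, x$F))
  invisible(x)
}

#' Formaldehyde-dependent per-capita death rate
#'
#' `H(x, F) = alpha * (F - b * x)` for cells whose tolerance `x` is below
#' the medium concentration `F`, and 0 for cells at or above it.  With
#' `0 <= b <= 1` the rate is strictly positive whenever `x < F`: lower-
#' tolerance cells die faster, with the strength of that dependence set by
#' `b` (at `b = 0` all sub-threshold cells die at the same rate
#' `alpha * F`).
#'
#' @param x Tolerance level(s), mM.
#' @param F Medium formaldehyde concentration, mM.
#' @param alpha,b Death parameters (see [model_parameters()]).
#' @return Per-capita death rate(s), 1/h.
#' @examples
#' death_rate(0, F = 4, alpha = 0.202, b = 0.770)  # 0.808
#' death_rate(5, F = 4, alpha = 0.202, b = 0.770)  # 0: above threshold
#' @export
death_rate <- function(x, F, alpha, b) {
  ifelse(x < F, alpha * (F - b * x), 0)
}

#' Right-hand-side operator of the semi-discretized dynamics
#'
#' Discretizes the structured-population equation on `grid` by the method of
#' lines: pointwise growth and death, second-order central-difference
#' diffusion, and first-order upwind advection, both transport terms in
#' conservative flux form with zero-flux boundaries at `x = 0` and `x = L`.
#' The `+ v dN/dx` advection term transports mass toward lower tolerance for
#' `v > 0`, so its upwind donor cell sits on the high-tolerance side.
#'
#' @param grid A [tolerance_grid()].
#' @param params A [model_parameters()] object.
#' @return A function `f(N)` returning `dN/dt` for a density vector `N`.
#' @export
assemble_operators <- function(grid, params) {
  stopifnot(inherits(grid, "tolerance_grid"),
            inherits(params, "model_parameters"))
  dx <- grid$dx
  n <- grid$n
  net_rate <- params$r_c - death_rate(grid$x, params$F, params$alpha, params$b)
  D <- params$D
  v <- params$v
  function(N) {
    dN <- net_rate * N
    if (D > 0) {
      # interface fluxes -D dN/dx; outer interfaces carry zero flux
      jd <- -D * diff(N) / dx
      dN <- dN - (c(jd, 0) - c(0, jd)) / dx
    }
    if (v != 0) {
      # physical velocity is -v; donor cell is upwind of the flow
      donor <- if (v > 0) N[-1L] else N[-n]
      ja <- -v * donor
      dN <- dN - (c(ja, 0) - c(0, ja)) / dx
    }
    dN
  }
}

#' Simulate the tolerance-distribution dynamics
#'
#' Integrates the semi-discrete system (see [assemble_operators()]) with the
#' stiff-capable adaptive `lsoda` integrator, banded for the tridiagonal
#' coupling of neighbouring tolerance bins.  Times are on the simulation
#' clock: `times[1] = 0` corresponds to the timepoint whose measured
#' distribution supplies the initial condition (the 2-hour sample in the
#' standard experiments).
#'
#' @param init Initial density on `grid` (cells/mL per bin), non-negative.
#' @param params A [model_parameters()] object.
#' @param times Output times (h), sorted, starting at 0.
#' @param grid A [tolerance_grid()].
#' @param rtol,atol_scale Solver tolerances: relative `rtol`, and absolute
#'   tolerance `atol_scale * sum(init) / grid$n`.
#' @return An object of class `"phenodrift_sim"`: list with `grid`, `times`,
#'   `params`, and `densities`, an `n_times x n_bins` matrix with tiny
#'   solver undershoots clipped to zero (the unclipped solver state is kept
#'   in element `raw`).
#' @examples
#' g <- tolerance_grid(L = 12, dx = 0.1)
#' init <- make_initial_distribution(-1, N_total = 3e6, grid = g)
#' p <- model_parameters(r_c = 0.195, alpha = 0.202, b = 0.77, D = 0.019, F = 4)
#' sim <- simulate_dynamics(init, p, times = c(0, 10, 20), grid = g)
#' @export
simulate_dynamics <- function(init, params, times, grid,
                              rtol = 1e-8, atol_scale = 1e-10) {
  check_density(init, grid)
  stopifnot(inherits(params, "model_parameters"),
            length(times) >= 1L, !is.unsorted(times), times[1] == 0)
  rhs <- assemble_operators(grid, params)
  atol <- atol_scale * max(sum(init), 1) / grid$n
  sol <- deSolve::ode.1D(
    y = init, times = times,
    func = function(t, y, p) list(rhs(y)),
    parms = NULL, nspec = 1L, method = "lsoda",
    rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration failed; solver diagnostics: istate = ",
         attr(sol, "istate")[1])
  }
  raw <- unname(sol[, -1L, drop = FALSE])
  if (any(!is.finite(raw))) stop("non-finite values in solver state")
  densities <- pmax(raw, 0)
  structure(
    list(grid = grid, times = times, params = params, densities = densities,
         raw = raw),
    class = "phenodrift_sim"
  )
}

#' @export
print.phenodrift_sim <- function(x, ...) {
  cat(sprintf(
    "Tolerance-distribution simulation: %d timepoints over %g h on [0, %g] mM (dx = %g)\n",
    length(x$times), max(x$times), x$grid$L, x$grid$dx))
  tot <- rowSums(x$densities)
  cat(sprintf("  total population: %.3g -> %.3g CFU/mL\n",
              tot[1], tot[length(tot)]))
  invisible(x)
}

#' Plot simulated tolerance distributions
#'
#' Cumulative distributions (CFU/mL able to grow at each tolerance level) at
#' each output time, on a log10 y-axis as the plating data are usually
#' displayed.
#'
#' @param x A `"phenodrift_sim"` object.
#' @param levels Coarse levels at which to display the cumulative counts;
#'   defaults to 1-mM steps.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.phenodrift_sim <- function(x, levels = seq(0, x$grid$L, by = 1), ...) {
  cum <- vapply(seq_along(x$times), function(i) {
    bin_to_data_resolution(x$densities[i, ], x$grid, levels)
  }, numeric(length(levels)))
  graphics::matplot(levels, pmax(cum, 1), type = "b", log = "y", pch = 16,
                    lty = 1, xlab = "Tolerance (mM)",
                    ylab = "CFU/mL (cumulative)", ...)
  graphics::legend("topright", legend = paste0(x$times, " h"),
                   col = seq_along(x$times), lty = 1, pch = 16, bty = "n")
  invisible(x)
}
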