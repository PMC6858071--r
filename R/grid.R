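#' Uniform grid over tolerance space
#'
#' Construct the discretization of the one-dimensional phenotype axis
#' (formaldehyde tolerance, mM) on which the structured-population model is
#' solved.  The lower boundary is pinned at 0 mM because tolerance cannot be
#' negative; the upper boundary `L` must sit above the highest tolerance
#' observed in the data the grid serves, so that upward phenotype transitions
#' are not artificially constrained.
#'
#' @param L Upper boundary of tolerance space (mM), `> 0`.
#' @param dx Grid step (mM).  The default, 0.01 mM, is the resolution at
#'   which the model is normally solved; coarser steps are useful for
#'   exploratory fitting.
#' @return An object of class `"tolerance_grid"`: a list with elements
#'   `x` (bin midpoint-free node positions, from 0 to `L`), `dx`, `L`,
#'   and `n` (number of nodes).
#' @examples
#' g <- tolerance_grid(L = 12, dx = 0.1)
#' g$n  # 121 nodes
#' @export
tolerance_grid <- function(L, dx = 0.01) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L), L > 0,
            is.numeric(dx), length(dx) == 1L, is.finite(dx), dx > 0, dx <= L)
  n <- round(L / dx) + 1L
  if (abs((n - 1L) * dx - L) > 1e-8 * max(1, L)) {
    stop("'L' must be an integer multiple of 'dx'")
  }
  structure(
    list(x = seq(0, by = dx, length.out = n), dx = dx, L = L, n = as.integer(n)),
    class = "tolerance_grid"
  )
}

#' @export
print.tolerance_grid <- function(x, ...) {
  cat(sprintf("Tolerance grid: [0, %g] mM, dx = %g mM, %d nodes\n",
              x$L, x$dx, x$n))
  invisible(x)
}

# internal: check that a numeric vector is a density on this grid
check_density <- function(values, grid) {
  stopifnot(inherits(grid, "tolerance_grid"))
  if (length(values) != grid$n) {
    stop(sprintf("density has %d values but grid has %d nodes",
                 length(values), grid$n))
  }
  if (any(!is.finite(values))) stop("density contains non-finite values")
  if (any(values < 0)) stop("density contains negative values")
  invisible(TRUE)
}
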