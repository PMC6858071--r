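#' Tolerance-distribution series: the canonical long format
#'
#' All plating data move through the package in one long-format data frame
#' with columns `condition` (e.g. `"selection"` or `"regrowth"`),
#' `substrate`, `replicate`, `time_h`, `tolerance_mM` and `cfu_per_ml`.
#' Each row is the cumulative count: CFU/mL able to form colonies on a
#' selective plate containing `tolerance_mM` formaldehyde, i.e. all cells
#' whose maximum tolerance is at least that level.
#'
#' @param path Path to a CSV file.  Extra columns are tolerated and kept.
#' @return A validated data frame in the canonical long format.
#' @seealso [average_replicates()], [extend_detection_limit()]
#' @export
read_tolerance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_series(df)
}

# internal: validate the canonical long format
validate_series <- function(df) {
  required <- c("condition", "substrate", "replicate", "time_h",
                "tolerance_mM", "cfu_per_ml")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!is.finite(df$cfu_per_ml)) || any(df$cfu_per_ml < 0)) {
    stop("'cfu_per_ml' must be finite and non-negative")
  }
  if (any(df$time_h < 0)) stop("'time_h' must be non-negative")
  df[order(df$replicate, df$time_h, df$tolerance_mM), , drop = FALSE]
}

#' Convert a cumulative tolerance distribution to phenotype density
#'
#' Selective plates count every cell whose maximum tolerance is at least the
#' plate concentration, so plated counts are cumulative from the right.  The
#' model instead tracks the number of cells whose maximum tolerance is
#' exactly each level.  The two are related by differencing at the data step
#' `h`: `N(x) = Nhat(x) - Nhat(x + h)`, with all remaining mass at the top
#' level assigned to that level.
#'
#' @param counts Cumulative CFU/mL, one value per level, non-increasing.
#' @param levels Tolerance levels (mM), ascending, equally spaced.
#' @return Numeric vector of the same length: cells per mL whose maximum
#'   tolerance falls at each level.
#' @examples
#' cumulative_to_density(c(100, 60, 10, 0), levels = 0:3)
#' @export
cumulative_to_density <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels), length(counts) >= 1L,
            !is.unsorted(levels, strictly = TRUE))
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("cumulative counts must be finite and non-negative")
  }
  if (any(diff(counts) > 0)) {
    stop("cumulative counts increase with tolerance level; ",
         "average or monotonize replicates before differencing")
  }
  c(-diff(counts), counts[length(counts)])
}

#' Convert a phenotype density back to the cumulative distribution
#'
#' Exact inverse of [cumulative_to_density()]: the cumulative count at a
#' level is the sum of the density at that level and above, matching what a
#' selective plate at that concentration would measure.
#'
#' @param density Non-negative cells/mL per level.
#' @return Cumulative counts, same length, non-increasing.
#' @examples
#' density_to_cumulative(c(40, 50, 10, 0))
#' @export
density_to_cumulative <- function(density) {
  if (any(!is.finite(density)) || any(density < 0)) {
    stop("density must be finite and non-negative")
  }
  rev(cumsum(rev(density)))
}

#' Extend all-zero observations to compensate for the plating detection limit
#'
#' Serial-dilution plating cannot detect subpopulations rarer than about
#' 34 CFU/mL, so rare high-tolerance phenotypes can appear as zeros and their
#' later growth be mistaken for phenotype transitions.  The extension rule
#' compensates conservatively: at any (time, level) where *all* replicates
#' observed 0 colonies, one colony is credited to exactly one replicate --
#' but only if either (a) some replicate observed at least one colony at a
#' higher concentration at the same time, or (b) the level is the first one
#' beyond the last level with a nonzero observation.  One colony at the
#' lowest counted dilution corresponds to `cfu_one_colony` CFU/mL (90.9 at
#' the 10 uL-spot, 10-fold-dilution plating scheme).
#'
#' The operation is idempotent (credited entries are flagged in an
#' `extended` column and never re-counted as observations) and modifies at
#' most one replicate per (time, level).
#'
#' @param df Series in the canonical long format (see [read_tolerance_csv()]).
#' @param cfu_one_colony CFU/mL equivalent of a single colony for the
#'   replicate that is credited.  Default 90.9.
#' @return The series with extended counts and a logical `extended` column.
#' @export
extend_detection_limit <- function(df, cfu_one_colony = 90.9) {
  df <- validate_series(df)
  if (is.null(df$extended)) df$extended <- FALSE
  groups <- split(seq_len(nrow(df)),
                  list(df$condition, df$substrate, df$time_h), drop = TRUE)
  for (idx in groups) {
    block <- df[idx, ]
    levels <- sort(unique(block$tolerance_mM))
    # only genuine (non-credited) colonies count as observations
    nz_by_level <- vapply(levels, function(l) {
      sel <- block$tolerance_mM == l
      any(block$cfu_per_ml[sel] > 0 & !block$extended[sel])
    }, logical(1))
    last_nz <- if (any(nz_by_level)) max(which(nz_by_level)) else 0L
    for (j in seq_along(levels)) {
      if (nz_by_level[j]) next
      rows <- idx[block$tolerance_mM == levels[j]]
      if (any(df$extended[rows])) next   # already credited
      higher_nz <- j < length(levels) && any(nz_by_level[(j + 1):length(levels)])
      first_beyond <- j == last_nz + 1L
      if (higher_nz || first_beyond) {
        df$cfu_per_ml[rows[1L]] <- cfu_one_colony
        df$extended[rows[1L]] <- TRUE
      }
    }
  }
  df
}

#' Average biological replicates of a tolerance-distribution series
#'
#' Arithmetic mean of CFU/mL across replicates at each (condition, substrate,
#' time, level).  The result carries a single pseudo-replicate `"mean"`.
#'
#' @param df Series in the canonical long format.
#' @return Averaged series with one record per (time, level).
#' @examples
#' # a level observed as 0, 0 and 90.9 CFU/mL averages to 30.3 CFU/mL
#' @export
average_replicates <- function(df) {
  df <- validate_series(df)
  key <- interaction(df$condition, df$substrate, df$time_h, df$tolerance_mM,
                     drop = TRUE)
  n_levels_per_rep <- table(df$replicate, key)
  if (any(n_levels_per_rep > 1)) {
    stop("duplicate (time, level) entries within a replicate")
  }
  if (length(unique(rowSums(n_levels_per_rep > 0))) > 1) {
    stop("replicates do not share the same (time, level) sets")
  }
  agg <- stats::aggregate(cfu_per_ml ~ condition + substrate + time_h +
                            tolerance_mM, data = df, FUN = mean)
  agg$replicate <- "mean"
  validate_series(agg[, c("condition", "substrate", "replicate", "time_h",
                          "tolerance_mM", "cfu_per_ml")])
}

#' Interpolate a coarse cumulative distribution onto the model grid
#'
#' The plating data resolve tolerance at 1- or 2-mM steps while the model is
#' solved at `grid$dx` (0.01 mM by default).  A monotone (Hyman-filtered)
#' cubic spline is fitted through the coarse cumulative counts and evaluated
#' on the fine grid; beyond the last data level the cumulative count is held
#' at its final value.  The fine cumulative curve is then differenced at
#' `grid$dx` to give the phenotype density used as the model's initial
#' condition.  The telescoping structure of the differencing guarantees that
#' the total density mass equals the cumulative count at level 0.
#'
#' @param counts Cumulative CFU/mL at the coarse levels, non-increasing.
#'   Small inversions from plating noise should be removed first (e.g. by
#'   [average_replicates()] followed by `cummin`); this function insists on
#'   monotone input.
#' @param levels Coarse tolerance levels (mM), ascending, spanning the data.
#' @param grid A [tolerance_grid()] whose `L` is at least `max(levels)`.
#' @return Density vector on `grid` (cells/mL per bin).
#' @export
interpolate_initial_condition <- function(counts, levels, grid) {
  stopifnot(inherits(grid, "tolerance_grid"),
            length(counts) == length(levels), length(counts) >= 2L)
  if (any(diff(counts) > 0)) {
    stop("cumulative counts must be non-increasing; monotonize first")
  }
  if (grid$L < max(levels)) {
    stop("grid upper boundary is below the highest data level")
  }
  if (min(levels) > 0) stop("levels must start at 0")
  f <- stats::splinefun(levels, counts, method = "hyman")
  fine <- numeric(grid$n)
  inside <- grid$x <= max(levels)
  fine[inside] <- f(grid$x[inside])
  fine[!inside] <- counts[length(counts)]
  # Hyman filtering guarantees monotonicity; clip rounding-level noise only
  fine <- pmin(fine, counts[1])
  fine <- cummin(pmax(fine, 0))
  c(-diff(fine), fine[length(fine)])
}

#' Bin a fine-grid density to the data's coarse resolution
#'
#' Model output lives on the fine grid; the data live at 1- or 2-mM plate
#' levels.  Fine density is summed into coarse bins (bin i covers
#' `[level_i, level_{i+1})`, the last bin extending to the top of the grid),
#' conserving total mass exactly, and then accumulated from the right into
#' the cumulative form that selective plating measures.
#'
#' @param density Density vector on `grid`.
#' @param grid A [tolerance_grid()].
#' @param levels Coarse levels (mM), ascending; each must coincide with a
#'   grid node.
#' @param cumulative If `TRUE` (default) return the cumulative counts at
#'   `levels`; otherwise the coarse binned density.
#' @return Numeric vector, one value per coarse level.
#' @export
bin_to_data_resolution <- function(density, grid, levels, cumulative = TRUE) {
  check_density(density, grid)
  stopifnot(!is.unsorted(levels, strictly = TRUE))
  node <- round(levels / grid$dx)
  if (any(abs(node * grid$dx - levels) > 1e-8)) {
    stop("coarse levels must align with grid nodes")
  }
  if (max(levels) > grid$L) stop("coarse levels extend beyond the grid")
  edges <- c(node + 1, grid$n + 1)   # 1-based node index of each bin start
  coarse <- vapply(seq_along(levels), function(i) {
    sum(density[edges[i]:(edges[i + 1] - 1)])
  }, numeric(1))
  if (cumulative) density_to_cumulative(coarse) else coarse
}

#' Prepare a replicate-level series for model fitting
#'
#' Convenience wrapper chaining the standard preparation steps: the
#' detection-limit extension ([extend_detection_limit()]), replicate
#' averaging ([average_replicates()]), and monotonization of each
#' timepoint's cumulative distribution by running minimum from the left
#' (the minimal correction for small plating inversions).
#'
#' @param df Series in the canonical long format with raw replicates.
#' @param extend Apply the detection-limit extension first?  Default `TRUE`.
#' @return Averaged, monotone series ready for [fit_tolerance_model()].
#' @export
prepare_series <- function(df, extend = TRUE) {
  if (extend) df <- extend_detection_limit(df)
  df <- average_replicates(df)
  groups <- split(seq_len(nrow(df)),
                  list(df$condition, df$substrate, df$time_h), drop = TRUE)
  for (idx in groups) {
    ord <- idx[order(df$tolerance_mM[idx])]
    df$cfu_per_ml[ord] <- cummin(df$cfu_per_ml[ord])
  }
  df
}
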