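# Small in-code fixtures shared across test files.

# A minimal long-format series: one condition, two timepoints, `reps`
# replicates, counts supplied per (time, level) as a named list of matrices
# (rows = replicates, cols = levels).
make_series <- function(counts_by_time, levels, reps = NULL,
                        condition = "selection", substrate = "methanol") {
  rows <- list()
  for (tm in names(counts_by_time)) {
    m <- counts_by_time[[tm]]
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
    for (r in seq_len(nrow(m))) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = condition, substrate = substrate,
        replicate = sprintf("rep%d", r), time_h = as.numeric(tm),
        tolerance_mM = levels, cfu_per_ml = m[r, ],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# random valid (non-increasing, non-negative) cumulative sequence
random_cumulative <- function(n, scale = 1e5) {
  sort(stats::runif(n, 0, scale), decreasing = TRUE)
}

# default selection-scenario generating parameters (best-supported model)
selection_params <- function() {
  model_parameters(r_c = 0.195, alpha = 0.202, b = 0.770, D = 0.019, F = 4)
}
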