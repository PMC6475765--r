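# Small fixtures shared across test files. Everything is generated in
# code; sizes are kept small so the whole suite stays fast.

# a small cohort with few ROIs for structural tests
small_cohort <- function(seed = 11L, n_roi = 6L, modality = "tau") {
  generate_cohort(simulation_params(
    modality, n_lpa = 6L, n_pca = 5L, n_control = 8L,
    n_roi = n_roi, seed = seed))
}

# a fast MCMC schedule for structural (non-calibration) tests
quick_spec <- function(seed = 1L, ...) {
  hier_spec("custom", n_chains = 2L, chain_length = 1500L,
            burn_in = 500L, thin = 5L, seed = seed, ...)
}

# observed annualized-change matrix of a cohort
change_matrix <- function(cohort) {
  attr(compute_annualized_changes(cohort), "change_matrix")
}

# brute-force partial correlation via lm() residuals, the independent
# oracle for the matrix implementation
oracle_partial_cor <- function(X, Y, covariates = NULL) {
  n <- nrow(X)
  resid_one <- function(v) {
    if (is.null(covariates)) stats::residuals(stats::lm(v ~ 1))
    else stats::residuals(stats::lm(v ~ ., data = as.data.frame(covariates)))
  }
  Xr <- apply(X, 2, resid_one)
  Yr <- apply(Y, 2, resid_one)
  out <- matrix(NA_real_, ncol(X), ncol(Y))
  for (i in seq_len(ncol(X)))
    for (j in seq_len(ncol(Y)))
      out[i, j] <- stats::cor(Xr[, i], Yr[, j])
  out
}
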