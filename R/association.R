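#' Partial Pearson correlation matrix between two ROI datasets
#'
#' Correlates every column of `X` with every column of `Y` after linearly
#' adjusting both for the covariates (with an intercept): each entry is
#' the Pearson correlation of the covariate residuals. With no
#' covariates this reduces to the plain Pearson correlation (columns are
#' still centered by the intercept).
#'
#' @param X,Y Numeric subjects x ROI matrices with matching rows.
#' @param covariates Optional subjects x k matrix/data frame (e.g. age at
#'   baseline, the default covariate elsewhere in the pipeline); `NULL`
#'   for none.
#' @return An object of class `association_result` with `r` (the
#'   correlation matrix), `covariates` (names) and `n`. Constant columns
#'   yield `NA` entries and a warning naming them — never a silent zero.
#' @export
partial_correlation_matrix <- function(X, Y, covariates = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (nrow(X) < k + 3L)
    stop("need at least k + 3 subjects for partial correlations",
         call. = FALSE)
  Xr <- residualize(X, covariates)
  Yr <- residualize(Y, covariates)
  r <- corr_cross(Xr, Yr)
  structure(list(
    r = r, p_adjusted = NULL, n_permutations = 0L,
    covariates = colnames(as.matrix(covariates %||% matrix(0, 1, 0))),
    n = nrow(X)
  ), class = "association_result")
}

# residuals of each column on [1, covariates]
residualize <- function(M, covariates) {
  M <- as.matrix(M)
  Z <- cbind(`(Intercept)` = rep(1, nrow(M)),
             if (!is.null(covariates)) as.matrix(covariates))
  qz <- qr(Z)
  M - Z %*% qr.coef(qz, M)
}

# cross-correlation of residual matrices; flags constant columns
corr_cross <- function(Xr, Yr) {
  sx <- sqrt(colSums(Xr^2))
  sy <- sqrt(colSums(Yr^2))
  bad_x <- sx <= .Machine$double.eps * nrow(Xr)
  bad_y <- sy <= .Machine$double.eps * nrow(Yr)
  if (any(bad_x) || any(bad_y))
    warning("constant column(s) after adjustment: ",
            paste(c(colnames(Xr)[bad_x] %||% which(bad_x),
                    colnames(Yr)[bad_y] %||% which(bad_y)),
                  collapse = ", "),
            "; correlations set to NA", call. = FALSE)
  sx[bad_x] <- NA_real_
  sy[bad_y] <- NA_real_
  crossprod(Xr, Yr) / outer(sx, sy)
}

#' Max-statistic permutation family-wise error correction
#'
#' Freedman-Lane-style maxT correction for the full partial-correlation
#' matrix: both datasets are residualized on the covariates, then for
#' each permutation the subject rows of the residualized `Y` are shuffled
#' and the maximum `|r|` over the whole matrix recorded. The adjusted
#' p-value of each entry is
#' `(1 + #\{permutation max >= |r_obs|\}) / (n_permutations + 1)`, so the
#' attainable minimum is `1/(n_permutations + 1)` and the family-wise
#' error rate is controlled at the nominal level under the global null.
#'
#' @inheritParams partial_correlation_matrix
#' @param n_permutations Number of row permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param return_unadjusted Also compute elementwise (uncorrected)
#'   permutation p-values from the same permutations.
#' @return An `association_result` with `r`, `p_adjusted`,
#'   `n_permutations`, and optionally `p_unadjusted`.
#' @export
permutation_fwe <- function(X, Y, covariates = NULL,
                            n_permutations = 1000L, seed = 1L,
                            return_unadjusted = FALSE) {
  if (n_permutations < 100L)
    stop("n_permutations must be >= 100", call. = FALSE)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n < 3L || (n <= 12L && factorial(n) <= n_permutations))
    stop("too few subjects (", n, ") for ", n_permutations,
         " distinct permutations", call. = FALSE)
  obs <- partial_correlation_matrix(X, Y, covariates)
  Xr <- residualize(X, covariates)
  Yr <- residualize(Y, covariates)
  r_abs <- abs(obs$r)
  Z <- cbind(rep(1, n), if (!is.null(covariates)) as.matrix(covariates))
  qz <- qr(Z)
  set.seed(seed)
  exceed_max <- matrix(0L, nrow(r_abs), ncol(r_abs))
  exceed_elem <- if (return_unadjusted) exceed_max
  for (b in seq_len(n_permutations)) {
    Yp <- Yr[sample.int(n), , drop = FALSE]
    # Freedman-Lane: re-residualize the permuted residuals on the
    # covariates so permuted and observed statistics share the same
    # projection
    Yp <- Yp - Z %*% qr.coef(qz, Yp)
    rp <- abs(corr_cross(Xr, Yp))
    mx <- max(rp, na.rm = TRUE)
    exceed_max <- exceed_max + (mx >= r_abs)
    if (return_unadjusted)
      exceed_elem <- exceed_elem + (rp >= r_abs)
  }
  obs$p_adjusted <- (1 + exceed_max) / (n_permutations + 1)
  dimnames(obs$p_adjusted) <- dimnames(obs$r)
  if (return_unadjusted) {
    obs$p_unadjusted <- (1 + exceed_elem) / (n_permutations + 1)
    dimnames(obs$p_unadjusted) <- dimnames(obs$r)
  }
  obs$n_permutations <- as.integer(n_permutations)
  obs
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> %dx%d correlations, n=%d%s%s\n",
    nrow(x$r), ncol(x$r), x$n,
    if (length(x$covariates)) paste0(", covariates: ",
                                     paste(x$covariates, collapse = ", "))
    else ", no covariates",
    if (x$n_permutations > 0)
      sprintf(", maxT-adjusted over %d permutations", x$n_permutations)
    else ""))
  invisible(x)
}

#' Sparse canonical correlation analysis by penalized matrix decomposition
#'
#' Finds L1-penalized weight vectors `u`, `v` maximizing the correlation
#' between `X u` and `Y v`. Both datasets are column-standardized
#' internally and the cross-covariance `Z = X'Y/(n-1)` decomposed by
#' alternating soft-thresholded power iterations:
#' `u <- normalize(soft(Z v, delta_u))` with `delta_u` found by binary
#' search so that `||u||_1 <= penalty_x * sqrt(ncol(X))` (the constraint
#' met with equality when active), and symmetrically for `v`. Further
#' components are obtained by deflating `Z` by `d u v'` with
#' `d = u'Z v`. Each pair is oriented so its largest-magnitude `u` entry
#' is positive.
#'
#' @param X,Y Numeric subjects x ROI matrices with matching rows.
#' @param penalty_x,penalty_y Lasso penalties in `(0, 1]`; the study
#'   default is 0.2 for both. Penalty 1 makes the constraint inactive,
#'   recovering the leading singular vectors of `Z`.
#' @param n_components Number of canonical pairs.
#' @param seed Seed (only used for optional random restarts;
#'   initialization itself is the deterministic leading right singular
#'   vector of `Z`).
#' @param n_restarts Extra random initializations per component; the
#'   iterate with the largest `|u'Z v|` wins.
#' @param tol,max_iter Convergence tolerance on the weight updates and
#'   iteration cap; non-convergence returns the best iterate flagged
#'   `converged = FALSE`.
#' @return A list of class `scca_result`; each element is a
#'   `canonical_pair` with `u`, `v`, `d` (`u'Z v`), `correlation`
#'   (Pearson correlation of `X u` and `Y v`), penalties and a
#'   `converged` flag.
#' @export
scca <- function(X, Y, penalty_x = 0.2, penalty_y = 0.2,
                 n_components = 1L, seed = 1L, n_restarts = 0L,
                 tol = 1e-6, max_iter = 200L) {
  stopifnot(penalty_x > 0, penalty_x <= 1, penalty_y > 0, penalty_y <= 1)
  X <- scale(as.matrix(X)); Y <- scale(as.matrix(Y))
  if (penalty_x * sqrt(ncol(X)) < 1 || penalty_y * sqrt(ncol(Y)) < 1)
    stop("penalty below the feasibility floor 1/sqrt(n columns): ",
         "an L2-unit weight vector always has L1 norm >= 1",
         call. = FALSE)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  Z <- crossprod(X, Y) / (n - 1)
  if (any(!is.finite(Z)))
    stop("constant column(s) make the cross-covariance undefined",
         call. = FALSE)
  if (all(abs(Z) < .Machine$double.eps))
    stop("cross-covariance is identically zero", call. = FALSE)
  cu <- penalty_x * sqrt(ncol(X))
  cv <- penalty_y * sqrt(ncol(Y))
  set.seed(seed)
  out <- vector("list", n_components)
  for (comp in seq_len(n_components)) {
    sv <- svd(Z, nu = 1, nv = 1)
    starts <- c(list(sv$v[, 1]),
                if (n_restarts > 0)
                  replicate(n_restarts,
                            normalize_l2(stats::rnorm(ncol(Z))),
                            simplify = FALSE))
    best <- NULL
    for (v0 in starts) {
      fit <- pmd_pair(Z, v0, cu, cv, tol, max_iter)
      if (is.null(best) || abs(fit$d) > abs(best$d)) best <- fit
    }
    # orient: largest-|u| entry positive
    iu <- which.max(abs(best$u))
    if (best$u[iu] < 0) {
      best$u <- -best$u; best$v <- -best$v
    }
    xu <- X %*% best$u
    yv <- Y %*% best$v
    best$correlation <- if (stats::sd(xu) > 0 && stats::sd(yv) > 0)
      stats::cor(xu, yv)[1] else NA_real_
    best$penalty_x <- penalty_x
    best$penalty_y <- penalty_y
    names(best$u) <- colnames(X)
    names(best$v) <- colnames(Y)
    class(best) <- "canonical_pair"
    out[[comp]] <- best
    Z <- Z - best$d * tcrossprod(best$u, best$v)
  }
  structure(out, class = "scca_result")
}

# one penalized rank-1 factor of Z by alternating soft-thresholding
pmd_pair <- function(Z, v0, cu, cv, tol, max_iter) {
  v <- normalize_l2(v0)
  u <- soft_unit(Z %*% v, cu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    u_new <- soft_unit(Z %*% v, cu)
    v_new <- soft_unit(crossprod(Z, u_new), cv)
    delta <- max(max(abs(u_new - u)), max(abs(v_new - v)))
    u <- u_new; v <- v_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  list(u = as.numeric(u), v = as.numeric(v),
       d = as.numeric(crossprod(u, Z %*% v)), converged = converged)
}

normalize_l2 <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm > 0) x / nrm else x
}

soft <- function(x, delta) sign(x) * pmax(abs(x) - delta, 0)

# soft-threshold then L2-normalize, with delta chosen by binary search
# so ||out||_1 <= c (equality when the constraint is active)
soft_unit <- function(x, c1) {
  x <- as.numeric(x)
  out <- normalize_l2(soft(x, 0))
  if (sum(abs(out)) <= c1 + 1e-12) return(out)
  lo <- 0
  hi <- max(abs(x))
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    out <- normalize_l2(soft(x, mid))
    l1 <- sum(abs(out))
    if (abs(l1 - c1) < 1e-10) break
    if (l1 > c1) lo <- mid else hi <- mid
  }
  normalize_l2(soft(x, (lo + hi) / 2))
}

#' @export
print.canonical_pair <- function(x, ...) {
  cat(sprintf(
    "<canonical_pair> correlation %.3f; %d/%d nonzero u, %d/%d nonzero v%s\n",
    x$correlation, sum(x$u != 0), length(x$u), sum(x$v != 0),
    length(x$v), if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Export canonical weights as a per-ROI value table
#'
#' One row per ROI and dataset with the canonical weight, suitable for
#' color-coding an atlas in any viewer (nonzero weight = colored ROI).
#'
#' @param pairs An `scca_result`.
#' @param roi_ids_x,roi_ids_y ROI identifiers for the two datasets.
#' @return A data frame (`component`, `dataset`, `roi`, `weight`).
#' @export
canonical_weight_table <- function(pairs, roi_ids_x = NULL,
                                   roi_ids_y = NULL) {
  do.call(rbind, lapply(seq_along(pairs), function(k) {
    p <- pairs[[k]]
    rbind(
      data.frame(component = k, dataset = "x",
                 roi = roi_ids_x %||% seq_along(p$u), weight = p$u),
      data.frame(component = k, dataset = "y",
                 roi = roi_ids_y %||% seq_along(p$v), weight = p$v))
  }))
}
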