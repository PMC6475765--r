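#' Specification of the hierarchical change model and its MCMC schedule
#'
#' Defines the Bayesian hierarchical model of regional annualized change:
#' for subject `i` in group `g(i)` and ROI `r`,
#' `y[i,r] = alpha[g(i),r] + beta[g(i),r] * x_i + eps`, with
#' `x_i = (age_i - age_center)/age_scale` (baseline age centered at 65
#' and scaled by decade), regional random intercepts
#' `alpha[g,.] ~ Normal(mu_alpha[g], tau_alpha[g])`, regional age effects
#' `beta[g,.] ~ Normal(mu_beta[g], tau_beta[g])`, and residual
#' `eps ~ Normal(0, sigma)`. Hypermeans carry standard-Normal priors and
#' all scales half-standard-Normal priors.
#'
#' Two MCMC profiles are packaged. `"paper"` is the full production
#' schedule: 200 parallel chains, 80,000 retained iterations each thinned
#' to every 40th value, after a 15,000-iteration burn-in — 400,000
#' retained draws in total. `"desk"` is the scaled-down profile used for
#' interactive work and the test suite: 4 chains, 10,000 retained
#' iterations thinned by 10 after 2,000 burn-in (4,000 retained draws).
#' `chain_length` counts post-burn-in iterations when
#' `post_burnin = TRUE` (the default reading); set `post_burnin = FALSE`
#' to read it as the total length including burn-in instead.
#'
#' @param profile `"desk"`, `"paper"` or `"custom"`.
#' @param n_chains,chain_length,thin,burn_in MCMC schedule (overrides the
#'   profile when given).
#' @param seed Master seed; chain `c` is seeded with
#'   `seed + 1000 * c`, giving distinct, overdispersed starting points.
#' @param age_center,age_scale Age centering (years) and scaling (years
#'   per unit; 10 = per decade).
#' @param hyper_mean_scale,hyper_sd_scale,resid_sd_scale Prior scales for
#'   the hypermeans (Normal), hyper-sds and residual sd (half-Normal).
#' @param per_region_sigma Use one residual sd per ROI instead of the
#'   default single shared sd.
#' @param post_burnin Whether `chain_length` counts post-burn-in
#'   iterations (default) or total iterations.
#' @return An object of class `hier_spec`.
#' @seealso [fit_mcmc()], [retained_draws()]
#' @export
#' @examples
#' retained_draws(hier_spec("paper"))  # 400000
hier_spec <- function(profile = c("desk", "paper", "custom"),
                      n_chains = NULL, chain_length = NULL, thin = NULL,
                      burn_in = NULL, seed = 1L,
                      age_center = 65, age_scale = 10,
                      hyper_mean_scale = 1, hyper_sd_scale = 1,
                      resid_sd_scale = 1,
                      per_region_sigma = FALSE, post_burnin = TRUE) {
  profile <- match.arg(profile)
  def <- switch(profile,
    desk  = list(n_chains = 4L, chain_length = 10000L, thin = 10L,
                 burn_in = 2000L),
    paper = list(n_chains = 200L, chain_length = 80000L, thin = 40L,
                 burn_in = 15000L),
    custom = list(n_chains = 4L, chain_length = 10000L, thin = 10L,
                  burn_in = 2000L))
  s <- list(
    profile = profile,
    n_chains = as.integer(n_chains %||% def$n_chains),
    chain_length = as.integer(chain_length %||% def$chain_length),
    thin = as.integer(thin %||% def$thin),
    burn_in = as.integer(burn_in %||% def$burn_in),
    seed = as.integer(seed),
    age_center = age_center, age_scale = age_scale,
    hyper_mean_scale = hyper_mean_scale,
    hyper_sd_scale = hyper_sd_scale,
    resid_sd_scale = resid_sd_scale,
    per_region_sigma = isTRUE(per_region_sigma),
    post_burnin = isTRUE(post_burnin)
  )
  stopifnot(s$thin >= 1L, s$n_chains >= 1L, s$burn_in >= 0L,
            s$hyper_sd_scale > 0, s$resid_sd_scale > 0)
  class(s) <- "hier_spec"
  s
}

#' Retained posterior draws implied by an MCMC schedule
#'
#' `n_chains * floor(L/thin)` where `L` is the post-burn-in chain length:
#' `chain_length` itself under the post-burn-in reading, or
#' `chain_length - burn_in` under the total-length reading.
#'
#' @param spec A [hier_spec()].
#' @return Integer count of retained draws.
#' @export
retained_draws <- function(spec) {
  stopifnot(inherits(spec, "hier_spec"))
  L <- if (spec$post_burnin) spec$chain_length
       else spec$chain_length - spec$burn_in
  if (L < spec$thin) stop("schedule retains no draws", call. = FALSE)
  spec$n_chains * (L %/% spec$thin)
}

#' Assemble the model design from a cohort and its annualized changes
#'
#' @param cohort A `cohort_table` (supplies ages and group labels).
#' @param changes The output of [compute_annualized_changes()] (long
#'   data frame with `subject_id`, `roi`, `change`), or a subjects x ROI
#'   matrix of annualized changes.
#' @param age_center,age_scale Centering (default 65 years) and scaling
#'   (default 10, i.e. per decade) for the baseline-age covariate.
#' @return A list of class `model_design`: `y` (n x R change matrix),
#'   `x` (centered/scaled age), `group` (factor), `roi_ids`, `groups`.
#' @export
#' @examples
#' coh <- generate_cohort(simulation_params("tau", seed = 7, n_roi = 4,
#'                        lobe_map = NULL))
#' d <- build_model_input(coh, compute_annualized_changes(coh))
#' range(d$x)
build_model_input <- function(cohort, changes, age_center = 65,
                              age_scale = 10) {
  stopifnot(inherits(cohort, "cohort_table"))
  subj <- cohort$subjects
  if (is.matrix(changes)) {
    y <- changes
  } else {
    stopifnot(all(c("subject_id", "roi", "change") %in% names(changes)))
    roi_ids <- sort(unique(changes$roi))
    y <- matrix(NA_real_, nrow(subj), length(roi_ids),
                dimnames = list(subj$subject_id, paste0("roi_", roi_ids)))
    y[cbind(match(changes$subject_id, subj$subject_id),
            match(changes$roi, roi_ids))] <- changes$change
    if (anyNA(y)) {
      bad <- which(is.na(y), arr.ind = TRUE)
      stop("missing annualized change for ",
           paste(sprintf("subject %s / ROI %s",
                         subj$subject_id[bad[, 1]],
                         roi_ids[bad[, 2]])[seq_len(min(5, nrow(bad)))],
                 collapse = "; "),
           if (nrow(bad) > 5) sprintf(" (and %d more)", nrow(bad) - 5),
           call. = FALSE)
    }
  }
  if (anyNA(subj$age_baseline)) stop("missing ages", call. = FALSE)
  groups <- intersect(group_levels(), unique(subj$group))
  structure(list(
    y = y,
    x = (subj$age_baseline - age_center) / age_scale,
    group = factor(subj$group, levels = groups),
    roi_ids = cohort$roi_ids,
    groups = groups
  ), class = "model_design")
}

#' Fit the hierarchical change model by MCMC
#'
#' Runs the packaged Gibbs sampler (conjugate normal block updates for the
#' regional intercepts/age effects and hypermeans; slice updates for the
#' half-Normal-prior scales) over `spec$n_chains` independent chains.
#' Each chain is seeded with `spec$seed + 1000 * chain` and initialized
#' overdispersed: hypermeans from Normal(0,1), scales from
#' `|Normal(0,1)| + 0.1`, regional effects from their group-level prior
#' at the drawn hyperparameters.
#'
#' @param spec A [hier_spec()].
#' @param design A `model_design` from [build_model_input()].
#' @return An object of class `posterior_draws`: arrays `alpha`, `beta`
#'   (`chain x draw x group x roi`), `mu_alpha`, `tau_alpha`, `mu_beta`,
#'   `tau_beta` (`chain x draw x group`), `sigma` (`chain x draw [x roi]`),
#'   plus `groups`, `roi_ids` and the `spec`.
#' @export
fit_mcmc <- function(spec, design) {
  stopifnot(inherits(spec, "hier_spec"), inherits(design, "model_design"))
  G <- length(design$groups)
  R <- ncol(design$y)
  if (G < 2L) stop("need >= 2 groups", call. = FALSE)
  if (R < 2L) stop("need >= 2 ROIs", call. = FALSE)
  if (any(table(design$group) < 2L))
    stop("degenerate design: every group needs >= 2 subjects",
         call. = FALSE)
  n_iter <- if (spec$post_burnin) spec$burn_in + spec$chain_length
            else spec$chain_length
  n_keep_chain <- retained_draws(spec) / spec$n_chains
  n_sig <- if (spec$per_region_sigma) R else 1L
  alpha <- array(NA_real_, c(spec$n_chains, n_keep_chain, G, R))
  beta <- array(NA_real_, c(spec$n_chains, n_keep_chain, G, R))
  hyp <- function() array(NA_real_, c(spec$n_chains, n_keep_chain, G))
  mu_a <- hyp(); tau_a <- hyp(); mu_b <- hyp(); tau_b <- hyp()
  sigma <- array(NA_real_, c(spec$n_chains, n_keep_chain, n_sig))
  gi <- as.integer(design$group) - 1L

  for (ch in seq_len(spec$n_chains)) {
    set.seed(spec$seed + 1000L * ch)
    ma <- stats::rnorm(G); mb <- stats::rnorm(G)
    ta <- abs(stats::rnorm(G)) + 0.1; tb <- abs(stats::rnorm(G)) + 0.1
    init <- list(
      alpha = matrix(stats::rnorm(G * R, ma, ta), G, R),
      beta = matrix(stats::rnorm(G * R, mb, tb), G, R),
      mu_alpha = ma, tau_alpha = ta, mu_beta = mb, tau_beta = tb,
      sigma = abs(stats::rnorm(n_sig)) + 0.1)
    out <- gibbs_chain(design$y, design$x, gi, G, n_iter, spec$burn_in,
                       spec$thin, init, spec$hyper_mean_scale,
                       spec$hyper_sd_scale, spec$resid_sd_scale,
                       spec$per_region_sigma)
    alpha[ch, , , ] <- array(out$alpha, c(n_keep_chain, G, R))
    beta[ch, , , ] <- array(out$beta, c(n_keep_chain, G, R))
    mu_a[ch, , ] <- out$mu_alpha; tau_a[ch, , ] <- out$tau_alpha
    mu_b[ch, , ] <- out$mu_beta; tau_b[ch, , ] <- out$tau_beta
    sigma[ch, , ] <- out$sigma
  }
  dn <- list(NULL, NULL, design$groups)
  dimnames(mu_a) <- dimnames(tau_a) <- dimnames(mu_b) <-
    dimnames(tau_b) <- dn
  structure(list(
    alpha = alpha, beta = beta,
    mu_alpha = mu_a, tau_alpha = tau_a,
    mu_beta = mu_b, tau_beta = tau_b, sigma = sigma,
    groups = design$groups, roi_ids = design$roi_ids, spec = spec
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "<posterior_draws> %d chains x %d draws; groups %s; %d ROIs\n",
    dim(x$alpha)[1], dim(x$alpha)[2],
    paste(x$groups, collapse = "/"), dim(x$alpha)[4]))
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split) R-hat: with `m` chains of `n` draws, within-chain
#' variance `W` (mean of per-chain variances) and between-chain variance
#' `B = n * var(chain means)`,
#' `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. Values near 1 indicate the
#' chains have mixed.
#'
#' @param draws A chains x draws matrix, or a `posterior_draws` object.
#' @param which For `posterior_draws`: `"hyper"` (hypermeans, hyper-sds
#'   and residual sd; the default) or `"all"` (additionally every
#'   regional intercept and age effect).
#' @return A single R-hat for a matrix; a named vector for
#'   `posterior_draws`.
#' @export
#' @examples
#' gelman_rubin(rbind(c(1, 2, 3), c(1, 2, 3)))  # sqrt(2/3)
gelman_rubin <- function(draws, which = c("hyper", "all")) {
  if (is.matrix(draws)) return(psrf(draws))
  stopifnot(inherits(draws, "posterior_draws"))
  which <- match.arg(which)
  out <- c()
  grab3 <- function(a, nm) {
    v <- vapply(seq_len(dim(a)[3]), function(k) psrf(a[, , k]),
                numeric(1))
    names(v) <- paste0(nm, "[", dimnames(a)[[3]] %||% seq_along(v), "]")
    v
  }
  for (nm in c("mu_alpha", "tau_alpha", "mu_beta", "tau_beta"))
    out <- c(out, grab3(draws[[nm]], nm))
  sig <- draws$sigma
  sv <- vapply(seq_len(dim(sig)[3]), function(k) psrf(sig[, , k]),
               numeric(1))
  names(sv) <- if (dim(sig)[3] == 1L) "sigma"
               else paste0("sigma[", seq_len(dim(sig)[3]), "]")
  out <- c(out, sv)
  if (which == "all") {
    for (nm in c("alpha", "beta")) {
      a <- draws[[nm]]
      for (g in seq_len(dim(a)[3])) {
        v <- vapply(seq_len(dim(a)[4]), function(r) psrf(a[, , g, r]),
                    numeric(1))
        names(v) <- sprintf("%s[%s,%d]", nm, draws$groups[g],
                            seq_len(dim(a)[4]))
        out <- c(out, v)
      }
    }
  }
  out
}

psrf <- function(mat) {
  m <- nrow(mat)
  n <- ncol(mat)
  if (m < 2L) stop("Gelman-Rubin needs >= 2 chains", call. = FALSE)
  if (n < 2L) stop("Gelman-Rubin needs >= 2 draws per chain",
                   call. = FALSE)
  W <- mean(apply(mat, 1, stats::var))
  B <- n * stats::var(rowMeans(mat))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Posterior draws of one group's regional effects
#'
#' @param draws A `posterior_draws`.
#' @param group Group label (`"LPA"`, `"PCA"`, `"CU"`).
#' @param parameter `"alpha"` (annualized-change intercepts at the age
#'   center) or `"beta"` (decade effects).
#' @return A `chain x draw x roi` array.
#' @export
group_effect_draws <- function(draws, group,
                               parameter = c("alpha", "beta")) {
  stopifnot(inherits(draws, "posterior_draws"))
  parameter <- match.arg(parameter)
  k <- match(group, draws$groups)
  if (is.na(k)) stop("group ", group, " not in the fit", call. = FALSE)
  a <- draws[[parameter]]
  out <- a[, , k, , drop = FALSE]
  dim(out) <- dim(a)[c(1, 2, 4)]
  out
}

#' Sample-size-weighted pooled atypical-AD effect
#'
#' Per posterior draw and ROI, the weighted average of the LPA and PCA
#' regional effects with weights equal to the group sample sizes:
#' `(n_lpa * theta_LPA + n_pca * theta_PCA) / (n_lpa + n_pca)`.
#'
#' @param draws A `posterior_draws` containing both patient groups.
#' @param n_lpa,n_pca Pooling weights (study defaults 18 and 12).
#' @param parameter `"alpha"` or `"beta"`.
#' @return A `chain x draw x roi` array of pooled draws.
#' @export
pooled_atypical_effect <- function(draws, n_lpa = 18, n_pca = 12,
                                   parameter = c("alpha", "beta")) {
  parameter <- match.arg(parameter)
  if (n_lpa + n_pca <= 0)
    stop("pooling weights sum to zero", call. = FALSE)
  a_lpa <- group_effect_draws(draws, "LPA", parameter)
  a_pca <- group_effect_draws(draws, "PCA", parameter)
  (n_lpa * a_lpa + n_pca * a_pca) / (n_lpa + n_pca)
}

#' Contrast patient effects against cognitively unimpaired controls
#'
#' Per posterior draw and ROI, subtracts the CU regional effect from a
#' patient effect (a group's own draws or the pooled atypical-AD draws),
#' i.e. the annualized change relative to cognitively unimpaired,
#' evaluated at the age center.
#'
#' @param effect_draws `chain x draw x roi` patient-effect array (from
#'   [group_effect_draws()] or [pooled_atypical_effect()]).
#' @param draws The `posterior_draws` the effects came from (must contain
#'   the CU group).
#' @param parameter `"alpha"` or `"beta"`.
#' @return A `chain x draw x roi` array of contrast draws.
#' @export
relative_to_controls <- function(effect_draws, draws,
                                 parameter = c("alpha", "beta")) {
  parameter <- match.arg(parameter)
  if (!"CU" %in% draws$groups)
    stop("no cognitively unimpaired group in the fit", call. = FALSE)
  effect_draws - group_effect_draws(draws, "CU", parameter)
}

#' Posterior region summaries (medians with 80% and 95% intervals)
#'
#' Empirical quantiles of the pooled (all chains) contrast draws per ROI,
#' using linear interpolation of order statistics. The defaults give the
#' posterior median with 80% (q10-q90) and 95% (q2.5-q97.5) intervals.
#'
#' @param contrast_draws A `chain x draw x roi` array (or draws x roi
#'   matrix).
#' @param probs Quantile probabilities.
#' @param roi_ids Optional ROI identifiers for the output.
#' @return A data frame with one row per ROI and one column per
#'   quantile (`median`, `q2.5`, `q10`, `q90`, `q97.5` under the default
#'   `probs`). If fewer than 100 draws are available a warning is issued
#'   and the attribute `low_draws` is set.
#' @export
summarize_regions <- function(contrast_draws,
                              probs = c(0.025, 0.10, 0.50, 0.90, 0.975),
                              roi_ids = NULL) {
  if (length(dim(contrast_draws)) == 3L) {
    d <- dim(contrast_draws)
    contrast_draws <- matrix(aperm(contrast_draws, c(2, 1, 3)),
                             d[1] * d[2], d[3])
  }
  low <- nrow(contrast_draws) < 100L
  if (low)
    warning("fewer than 100 retained draws: intervals will be unstable",
            call. = FALSE)
  q <- apply(contrast_draws, 2, stats::quantile, probs = probs,
             type = 7, names = FALSE)
  out <- as.data.frame(t(q))
  names(out) <- ifelse(probs == 0.5, "median",
                       paste0("q", format(100 * probs, trim = TRUE,
                                          drop0trailing = TRUE)))
  out <- cbind(roi = roi_ids %||% seq_len(nrow(out)), out)
  attr(out, "low_draws") <- low
  out
}
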