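test_that("design assembly centers age at 65 and scales by decade", {
  coh <- small_cohort(seed = 12L, n_roi = 3L)
  coh$subjects$age_baseline <- rep(c(65, 75, 53), length.out =
                                     nrow(coh$subjects))
  d <- build_model_input(coh, compute_annualized_changes(coh))
  expect_equal(d$x, rep(c(0, 1, -1.2), length.out = length(d$x)))
  expect_equal(dim(d$y), c(nrow(coh$subjects), 3L))
})

test_that("missing design cells are reported with subject and ROI", {
  coh <- small_cohort(seed = 12L, n_roi = 3L)
  ch <- compute_annualized_changes(coh)
  ch <- ch[!(ch$subject_id == coh$subjects$subject_id[2] & ch$roi == 3), ]
  expect_error(build_model_input(coh, ch),
               paste0("subject ", coh$subjects$subject_id[2], " / ROI 3"))
})

test_that("retained-draw bookkeeping matches the schedule readings", {
  # post-burn-in reading of the production schedule
  expect_identical(retained_draws(hier_spec("paper")), 400000L)
  # total-length reading of the same printed schedule
  expect_identical(
    retained_draws(hier_spec("paper", post_burnin = FALSE)),
    200L * ((80000L - 15000L) %/% 40L))
  expect_identical(retained_draws(hier_spec("desk")), 4L * 1000L)
  s <- quick_spec()
  expect_equal(retained_draws(s) / s$n_chains, 300)
})

test_that("Gelman-Rubin statistic matches hand computation", {
  # two identical chains: W = 1, B = 0, n = 3 -> sqrt(2/3)
  expect_equal(gelman_rubin(rbind(c(1, 2, 3), c(1, 2, 3))),
               sqrt(2 / 3))
  # separated means, tiny within-variance -> R-hat >> 1
  m <- rbind(rnorm(50, 0, 0.01), rnorm(50, 10, 0.01))
  expect_gt(gelman_rubin(m), 10)
  # long chains from one target -> near 1
  set.seed(2)
  m2 <- matrix(rnorm(4 * 20000), nrow = 4)
  expect_lt(abs(gelman_rubin(m2) - 1), 0.01)
  expect_error(gelman_rubin(matrix(1:5, nrow = 1)), ">= 2 chains")
})

test_that("noise-free data pins the regional intercepts to truth", {
  p <- simulation_params(
    "tau", n_lpa = 8L, n_pca = 6L, n_control = 10L, n_roi = 4L,
    seed = 9L,
    hyper_sd_intercept = c(LPA = 0, PCA = 0, CU = 0),
    hyper_sd_age = c(LPA = 0, PCA = 0, CU = 0),
    residual_sd = 1e-6)
  coh <- generate_cohort(p)
  d <- build_model_input(coh, compute_annualized_changes(coh))
  fit <- fit_mcmc(quick_spec(seed = 10L), d)
  for (g in c("LPA", "PCA", "CU")) {
    post_med <- apply(group_effect_draws(fit, g), 3, median)
    expect_lt(max(abs(post_med - p$hyper_mean_intercept[[g]])), 0.005)
  }
})

test_that("null data concentrates the hypermeans near zero", {
  coh <- small_cohort(seed = 14L, n_roi = 4L)
  d <- build_model_input(coh, compute_annualized_changes(coh))
  d$y[] <- 0
  fit <- fit_mcmc(quick_spec(seed = 3L), d)
  expect_lt(max(abs(apply(fit$mu_alpha, 3, median))), 0.01)
  expect_lt(max(abs(apply(fit$mu_beta, 3, median))), 0.01)
})

test_that("degenerate designs are rejected", {
  coh <- small_cohort(seed = 15L, n_roi = 4L)
  d <- build_model_input(coh, compute_annualized_changes(coh))
  d1 <- d
  keep <- c(which(d$group == "LPA")[1], which(d$group != "LPA"))
  d1$y <- d$y[keep, ]
  d1$x <- d$x[keep]
  d1$group <- d$group[keep]
  expect_error(fit_mcmc(quick_spec(), d1), "degenerate")
  d2 <- d
  d2$y <- d$y[, 1, drop = FALSE]
  expect_error(fit_mcmc(quick_spec(), d2), ">= 2 ROIs")
})

test_that("pooled atypical effect is the sample-size weighted average", {
  coh <- small_cohort(seed = 16L, n_roi = 3L)
  d <- build_model_input(coh, compute_annualized_changes(coh))
  fit <- fit_mcmc(quick_spec(seed = 4L), d)
  a_lpa <- group_effect_draws(fit, "LPA")
  a_pca <- group_effect_draws(fit, "PCA")
  # study sizes: (18 * 0.10 + 12 * 0.05) / 30 = 0.08 elementwise
  pooled <- pooled_atypical_effect(fit, 18, 12)
  expect_equal(pooled, (18 * a_lpa + 12 * a_pca) / 30)
  const_check <- (18 * 0.10 + 12 * 0.05) / 30
  expect_equal(const_check, 0.08)
  # equal weights -> simple average; zero PCA weight -> LPA unchanged
  expect_equal(pooled_atypical_effect(fit, 5, 5), (a_lpa + a_pca) / 2)
  expect_equal(pooled_atypical_effect(fit, 7, 0), a_lpa)
  expect_error(pooled_atypical_effect(fit, 0, 0), "zero")
})

test_that("contrast against controls is antisymmetric and truth-centered", {
  coh <- small_cohort(seed = 17L, n_roi = 4L)
  d <- build_model_input(coh, compute_annualized_changes(coh))
  fit <- fit_mcmc(quick_spec(seed = 5L), d)
  a_lpa <- group_effect_draws(fit, "LPA")
  a_cu <- group_effect_draws(fit, "CU")
  contr <- relative_to_controls(a_lpa, fit)
  expect_equal(contr, a_lpa - a_cu)
  # identical effects -> zero contrast
  expect_equal(relative_to_controls(a_cu, fit),
               array(0, dim(a_cu)), tolerance = 1e-12)
})

test_that("synthetic truth gap is recovered by the posterior contrast", {
  p <- simulation_params(
    "tau", n_roi = 6L, seed = 19L,
    hyper_mean_intercept = c(LPA = 0.11, PCA = 0.11, CU = 0.01),
    hyper_sd_intercept = c(LPA = 0.005, PCA = 0.005, CU = 0.005),
    hyper_mean_age = c(LPA = 0, PCA = 0, CU = 0),
    hyper_sd_age = c(LPA = 0.005, PCA = 0.005, CU = 0.005),
    residual_sd = 0.03)
  coh <- generate_cohort(p)
  d <- build_model_input(coh, compute_annualized_changes(coh))
  fit <- fit_mcmc(quick_spec(seed = 6L), d)
  contr <- relative_to_controls(pooled_atypical_effect(fit, 18, 12), fit)
  s <- summarize_regions(contr)
  expect_true(all(s$q2.5 < 0.10 & 0.10 < s$q97.5))
})

test_that("region summaries are ordered quantiles matching a sort oracle", {
  set.seed(33)
  draws <- array(rnorm(2 * 400 * 3), c(2, 400, 3))
  s <- summarize_regions(draws)
  expect_true(all(s$q2.5 <= s$q10 & s$q10 <= s$median &
                  s$median <= s$q90 & s$q90 <= s$q97.5))
  flat <- matrix(aperm(draws, c(2, 1, 3)), 800, 3)
  # independent computation from sorted draws (type-7 interpolation)
  oracle_q <- function(v, p) {
    v <- sort(v)
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[pmin(lo + 1, length(v))] - v[lo])
  }
  for (r in 1:3) {
    expect_equal(s$median[r], oracle_q(flat[, r], 0.5))
    expect_equal(s$q10[r], oracle_q(flat[, r], 0.10))
    expect_equal(s$q97.5[r], oracle_q(flat[, r], 0.975))
  }
  # constant draws collapse every quantile
  cd <- matrix(2.5, 200, 2)
  sc <- summarize_regions(cd)
  expect_true(all(as.matrix(sc[, -1]) == 2.5))
  expect_warning(summarize_regions(matrix(rnorm(50 * 2), 50, 2)),
                 "fewer than 100")
})

test_that("the Gibbs sampler agrees with an independent JAGS fit", {
  # small two-group fixture; both samplers target the same posterior
  library(rjags)
  p <- simulation_params(
    "tau", n_lpa = 12L, n_pca = 10L, n_control = 2L, n_roi = 6L,
    seed = 23L, residual_sd = 0.08)
  coh <- generate_cohort(p)
  d <- build_model_input(coh, compute_annualized_changes(coh))
  fit <- fit_mcmc(hier_spec("custom", n_chains = 4L,
                            chain_length = 10000L, burn_in = 2000L,
                            thin = 2L, seed = 29L), d)

  model_str <- "
  model {
    for (i in 1:n) {
      for (r in 1:R) {
        y[i, r] ~ dnorm(alpha[g[i], r] + beta[g[i], r] * x[i], prec)
      }
    }
    for (k in 1:G) {
      for (r in 1:R) {
        alpha[k, r] ~ dnorm(mu_a[k], prec_a[k])
        beta[k, r] ~ dnorm(mu_b[k], prec_b[k])
      }
      mu_a[k] ~ dnorm(0, 1)
      mu_b[k] ~ dnorm(0, 1)
      tau_a[k] ~ dnorm(0, 1) T(0,)
      tau_b[k] ~ dnorm(0, 1) T(0,)
      prec_a[k] <- 1 / (tau_a[k] * tau_a[k])
      prec_b[k] <- 1 / (tau_b[k] * tau_b[k])
    }
    sigma ~ dnorm(0, 1) T(0,)
    prec <- 1 / (sigma * sigma)
  }"
  jm <- jags.model(textConnection(model_str),
                   data = list(y = d$y, x = d$x,
                               g = as.integer(d$group),
                               n = nrow(d$y), R = ncol(d$y),
                               G = length(d$groups)),
                   n.chains = 2, quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 7))
  update(jm, 3000, progress.bar = "none")
  js <- coda.samples(jm, c("mu_a", "mu_b", "tau_a", "sigma"), 20000,
                     progress.bar = "none")
  jmat <- as.matrix(js)

  for (k in seq_along(d$groups)) {
    expect_lt(abs(mean(fit$mu_alpha[, , k]) -
                  mean(jmat[, sprintf("mu_a[%d]", k)])), 0.01)
    expect_lt(abs(sd(fit$mu_alpha[, , k]) -
                  sd(jmat[, sprintf("mu_a[%d]", k)])), 0.005)
    expect_lt(abs(mean(fit$tau_alpha[, , k]) -
                  mean(jmat[, sprintf("tau_a[%d]", k)])), 0.005)
  }
  expect_lt(abs(mean(fit$sigma) - mean(jmat[, "sigma"])), 0.003)
})
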