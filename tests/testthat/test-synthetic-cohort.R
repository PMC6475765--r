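test_that("cohort generation is deterministic under a fixed seed", {
  p <- simulation_params("tau", seed = 99L, n_roi = 5L)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$followup, b$followup)
  expect_identical(a$truth, b$truth)
  p2 <- simulation_params("tau", seed = 100L, n_roi = 5L)
  expect_false(identical(generate_cohort(p2)$followup, a$followup))
})

test_that("noise-free degenerate cohort reproduces the group intercepts", {
  p <- simulation_params(
    "tau", n_roi = 4L, seed = 3L,
    hyper_sd_intercept = c(LPA = 0, PCA = 0, CU = 0),
    hyper_sd_age = c(LPA = 0, PCA = 0, CU = 0),
    hyper_mean_age = c(LPA = 0, PCA = 0, CU = 0),
    residual_sd = 0, baseline_sd = 0)
  coh <- generate_cohort(p)
  ch <- change_matrix(coh)
  for (g in c("LPA", "PCA", "CU")) {
    rows <- coh$subjects$group == g
    expect_equal(unname(ch[rows, ]),
                 matrix(p$hyper_mean_intercept[[g]], sum(rows), 4L),
                 tolerance = 1e-12)
  }
})

test_that("empirical mean of observed changes matches the generative law", {
  # law-of-large-numbers check at n = 2000 subjects in one group
  p <- simulation_params(
    "tau", n_lpa = 2000L, n_pca = 2L, n_control = 2L, n_roi = 84L,
    seed = 21L,
    hyper_mean_intercept = c(LPA = 0.10, PCA = 0.05, CU = 0),
    hyper_mean_age = c(LPA = 0, PCA = 0, CU = 0),
    residual_sd = 0.05)
  coh <- generate_cohort(p)
  ch <- change_matrix(coh)
  lpa <- coh$subjects$group == "LPA"
  obs <- ch[lpa, ]
  # between-ROI spread is dominated by the drawn regional intercepts
  se <- sqrt(p$hyper_sd_intercept[["LPA"]]^2 / 84 +
             p$residual_sd^2 / length(obs))
  expect_lt(abs(mean(obs) - 0.10), 3 * se)
  # age slopes shift changes by beta * (age-65)/10: check the regression
  x <- (coh$subjects$age_baseline[lpa] - 65) / 10
  slope <- stats::coef(stats::lm(rowMeans(obs) ~ x))[2]
  expect_lt(abs(slope - mean(coh$truth$beta[, "LPA"])), 0.01)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_params("tau", hyper_sd_intercept =
                                   c(LPA = -1, PCA = 1, CU = 1)),
               ">= 0")
  expect_error(simulation_params("tau", residual_sd = -0.1), ">= 0")
  expect_error(simulation_params("tau", n_roi = 1L), "n_roi")
  expect_error(simulation_params("tau", residual_sd = c(0.1, 0.2)),
               "per ROI")
})

test_that("per-region residual structure is honoured", {
  sds <- c(rep(0.001, 2), rep(0.5, 2))
  p <- simulation_params("volume", n_lpa = 400L, n_pca = 2L,
                         n_control = 2L, n_roi = 4L, seed = 8L,
                         residual_sd = sds,
                         hyper_sd_intercept = c(LPA = 0, PCA = 0, CU = 0),
                         hyper_sd_age = c(LPA = 0, PCA = 0, CU = 0),
                         hyper_mean_age = c(LPA = 0, PCA = 0, CU = 0))
  coh <- generate_cohort(p)
  ch <- change_matrix(coh)[coh$subjects$group == "LPA", ]
  emp <- apply(ch, 2, sd)
  expect_lt(max(emp[1:2]), 0.01)
  expect_gt(min(emp[3:4]), 0.3)
})

test_that("cohort CSV round-trips and truth sidecar is written", {
  coh <- small_cohort(seed = 5L)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort_csv(coh, path)
  expect_true(file.exists(paste0(path, ".truth.json")))
  back <- read_cohort_csv(path)
  expect_equal(back$baseline, coh$baseline)
  expect_equal(back$followup, coh$followup)
  expect_equal(back$subjects$group, coh$subjects$group)
})

test_that("a corrupt cohort CSV fails fast with a named column", {
  coh <- small_cohort(seed = 6L)
  path <- file.path(withr::local_tempdir(), "cohort.csv")
  write_cohort_csv(coh, path)
  long <- utils::read.csv(path)
  long$interval_days <- NULL
  utils::write.csv(long, path, row.names = FALSE)
  expect_error(read_cohort_csv(path), "interval_days")
})

test_that("phantom construction round-trips ROI medians exactly", {
  ph <- generate_phantom(n_roi = 10L, reference_median = 2,
                         shape = c(12L, 12L, 4L), seed = 31L,
                         followup_scale = 1.1)
  med <- phantom_roi_medians(ph$baseline, reference_id = ph$reference_id)
  expect_identical(unname(med$roi_medians), ph$baseline$truth$median)
  expect_identical(med$reference_median, 2)
  fmed <- phantom_roi_medians(ph$followup, reference_id = ph$reference_id)
  expect_identical(unname(fmed$roi_medians), ph$baseline$truth$median * 1.1)
})

test_that("phantom rejects a volume too small for the label blocks", {
  expect_error(generate_phantom(n_roi = 84L, shape = c(4L, 4L, 4L)),
               "too small")
})

test_that("phantom volumes survive a NIfTI round-trip", {
  ph <- generate_phantom(n_roi = 6L, reference_median = 1.5,
                         shape = c(10L, 10L, 4L), seed = 13L)
  dir <- withr::local_tempdir()
  write_phantom_nifti(ph$baseline, dir, "bl")
  back <- read_phantom_nifti(dir, "bl")
  expect_equal(back$uptake, ph$baseline$uptake, tolerance = 1e-6)
  expect_identical(back$labels, ph$baseline$labels)
  med <- phantom_roi_medians(back, reference_id = ph$reference_id)
  expect_equal(unname(med$roi_medians), ph$baseline$truth$median,
               tolerance = 1e-6)
})
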