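#' Simulation parameters for a synthetic longitudinal cohort
#'
#' Bundles the generative settings for [generate_cohort()]. The defaults
#' mirror the study design the package targets: 18 logopenic progressive
#' aphasia (LPA) and 12 posterior cortical atrophy (PCA) patients plus 45
#' cognitively unimpaired (CU) controls, 84 atlas ROIs, baseline ages
#' uniform on 53-80 years and scan intervals uniform on 348-406 days.
#' Group-level hyperparameters are given per modality:
#'
#' * `"tau"` — values are SUVR; regional mean annualized accumulation of
#'   0.08 (LPA) / 0.07 (PCA) SUVR/yr against 0.01 in controls, with
#'   negative age effects (younger patients accumulate faster).
#' * `"volume"` — values are grey-matter volume as a percentage of each
#'   subject's baseline (baseline = 100), so the annualized change is in
#'   %/yr, the scale of an annualized log-Jacobian; mean atrophy of
#'   -1.5 %/yr in patients against -0.3 in controls, with positive age
#'   effects (older patients atrophy more slowly).
#'
#' @param modality `"tau"` or `"volume"`; selects the default
#'   hyperparameters above. All can be overridden.
#' @param n_lpa,n_pca,n_control Group sizes.
#' @param n_roi Number of ROIs (>= 2).
#' @param lobe_map ROI-to-lobe assignment; defaults to
#'   [default_lobe_map()] (must cover `n_roi` ROIs).
#' @param hyper_mean_intercept,hyper_sd_intercept Named vectors
#'   (`LPA`, `PCA`, `CU`): mean and sd of the Normal from which each
#'   group's per-ROI true annualized-change intercepts are drawn
#'   (change-units/yr).
#' @param hyper_mean_age,hyper_sd_age Same, for the per-ROI baseline-age
#'   slopes (change-units/yr per decade, age centered at 65).
#' @param residual_sd Annualized residual sd; a scalar (shared across
#'   regions, the default structure) or a length-`n_roi` vector
#'   (per-region).
#' @param baseline_mean,baseline_sd Normal parameters for the baseline
#'   value of each subject x ROI cell.
#' @param age_distribution,interval_distribution Length-2 `(min, max)`
#'   vectors: uniform ranges for baseline age (years) and scan interval
#'   (days).
#' @param seed Integer seed making the cohort reproducible.
#' @return An object of class `simulation_params`.
#' @export
#' @examples
#' p <- simulation_params("tau", seed = 1)
#' p$n_lpa
simulation_params <- function(modality = c("tau", "volume"),
                              n_lpa = 18L, n_pca = 12L, n_control = 45L,
                              n_roi = 84L,
                              lobe_map = NULL,
                              hyper_mean_intercept = NULL,
                              hyper_sd_intercept = NULL,
                              hyper_mean_age = NULL,
                              hyper_sd_age = NULL,
                              residual_sd = NULL,
                              baseline_mean = NULL,
                              baseline_sd = NULL,
                              age_distribution = c(53, 80),
                              interval_distribution = c(348, 406),
                              seed = 1L) {
  modality <- match.arg(modality)
  defaults <- if (modality == "tau") {
    list(hmi = c(LPA = 0.08, PCA = 0.07, CU = 0.01),
         hsi = c(LPA = 0.03, PCA = 0.03, CU = 0.02),
         hma = c(LPA = -0.03, PCA = -0.03, CU = 0),
         hsa = c(LPA = 0.02, PCA = 0.02, CU = 0.01),
         res = 0.05, bmu = 1.3, bsd = 0.15)
  } else {
    list(hmi = c(LPA = -1.5, PCA = -1.5, CU = -0.3),
         hsi = c(LPA = 0.5, PCA = 0.5, CU = 0.2),
         hma = c(LPA = 0.4, PCA = 0.4, CU = 0),
         hsa = c(LPA = 0.2, PCA = 0.2, CU = 0.1),
         res = 0.8, bmu = 100, bsd = 2)
  }
  p <- list(
    modality = modality,
    n_lpa = as.integer(n_lpa), n_pca = as.integer(n_pca),
    n_control = as.integer(n_control), n_roi = as.integer(n_roi),
    lobe_map = lobe_map,
    hyper_mean_intercept = hyper_mean_intercept %||% defaults$hmi,
    hyper_sd_intercept = hyper_sd_intercept %||% defaults$hsi,
    hyper_mean_age = hyper_mean_age %||% defaults$hma,
    hyper_sd_age = hyper_sd_age %||% defaults$hsa,
    residual_sd = residual_sd %||% defaults$res,
    baseline_mean = baseline_mean %||% defaults$bmu,
    baseline_sd = baseline_sd %||% defaults$bsd,
    age_distribution = as.numeric(age_distribution),
    interval_distribution = as.numeric(interval_distribution),
    seed = as.integer(seed)
  )
  class(p) <- "simulation_params"
  validate_simulation_params(p)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

group_levels <- function() c("LPA", "PCA", "CU")

validate_simulation_params <- function(p) {
  for (nm in c("hyper_sd_intercept", "hyper_sd_age")) {
    v <- p[[nm]]
    if (!all(group_levels() %in% names(v)))
      stop(nm, " must be named with LPA, PCA, CU", call. = FALSE)
    if (any(v < 0)) stop(nm, " must be >= 0", call. = FALSE)
  }
  if (any(p$residual_sd < 0))
    stop("residual_sd must be >= 0", call. = FALSE)
  if (!length(p$residual_sd) %in% c(1L, p$n_roi))
    stop("residual_sd must be a scalar or one value per ROI",
         call. = FALSE)
  if (p$n_roi < 2L) stop("n_roi must be >= 2", call. = FALSE)
  if (!is.null(p$lobe_map)) validate_lobe_map(p$lobe_map, p$n_roi)
  if (diff(p$age_distribution) < 0 || diff(p$interval_distribution) <= 0)
    stop("distribution ranges must satisfy min <= max", call. = FALSE)
  invisible(p)
}

#' Generate a synthetic two-timepoint ROI cohort with recorded truth
#'
#' Draws a cohort from the generative form of the hierarchical change
#' model. For each group `g` and ROI `r` a true intercept
#' `alpha[g,r] ~ Normal(hyper_mean_intercept[g], hyper_sd_intercept[g])`
#' and age slope `beta[g,r] ~ Normal(hyper_mean_age[g], hyper_sd_age[g])`
#' are drawn once; subject `i`'s true annualized change in ROI `r` is
#' `alpha[g(i),r] + beta[g(i),r] * (age_i - 65)/10`. Measurement noise
#' enters the follow-up value only, so the observed annualized change is
#' the true change plus `Normal(0, residual_sd)` noise:
#' `followup = baseline + (true + noise) * interval_days/365.25`.
#'
#' @param params A [simulation_params()] object.
#' @param subjects Optional data frame (`subject_id`, `group`,
#'   `age_baseline`, `interval_days`) to reuse subject-level draws across
#'   modalities; by default subjects are drawn from `params`.
#' @return An object of class `cohort_table`: a list with `subjects`,
#'   `baseline` and `followup` (subjects x ROI matrices), `modality`,
#'   `roi_ids`, `lobe_map`, `params`, and `truth` (the drawn `alpha`,
#'   `beta` and the true per-subject change matrix).
#' @export
#' @examples
#' coh <- generate_cohort(simulation_params("tau", seed = 42))
#' dim(coh$baseline)
generate_cohort <- function(params, subjects = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  validate_simulation_params(params)
  set.seed(params$seed)
  g <- group_levels()
  if (is.null(subjects)) {
    n <- c(params$n_lpa, params$n_pca, params$n_control)
    subjects <- data.frame(
      subject_id = sprintf("S%03d", seq_len(sum(n))),
      group = rep(g, n),
      age_baseline = stats::runif(sum(n), params$age_distribution[1],
                                  params$age_distribution[2]),
      interval_days = stats::runif(sum(n), params$interval_distribution[1],
                                   params$interval_distribution[2]),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(subjects$interval_days > 0),
            all(subjects$group %in% g))
  R <- params$n_roi
  ns <- nrow(subjects)
  alpha <- sapply(g, function(k)
    stats::rnorm(R, params$hyper_mean_intercept[[k]],
                 params$hyper_sd_intercept[[k]]))
  beta <- sapply(g, function(k)
    stats::rnorm(R, params$hyper_mean_age[[k]], params$hyper_sd_age[[k]]))
  x <- (subjects$age_baseline - 65) / 10
  gi <- match(subjects$group, g)
  true_change <- t(alpha)[gi, , drop = FALSE] +
    t(beta)[gi, , drop = FALSE] * x
  years <- subjects$interval_days / 365.25
  baseline <- matrix(
    stats::rnorm(ns * R, params$baseline_mean, params$baseline_sd),
    ns, R)
  noise <- matrix(stats::rnorm(ns * R), ns, R) *
    rep(params$residual_sd, length.out = R)[col(matrix(0, ns, R))]
  followup <- baseline + (true_change + noise) * years
  if (params$modality == "tau" && any(baseline <= 0 | followup <= 0))
    stop("generated SUVR values must be positive; ",
         "check baseline_mean/baseline_sd", call. = FALSE)
  roi_ids <- seq_len(R)
  dimnames(baseline) <- dimnames(followup) <-
    list(subjects$subject_id, paste0("roi_", roi_ids))
  structure(list(
    subjects = subjects,
    baseline = baseline,
    followup = followup,
    modality = params$modality,
    roi_ids = roi_ids,
    lobe_map = params$lobe_map,
    params = params,
    truth = list(alpha = alpha, beta = beta, true_change = true_change)
  ), class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d subjects (%s) x %d ROIs, modality %s\n",
    nrow(x$subjects),
    paste(sprintf("%s=%d", names(table(x$subjects$group)),
                  table(x$subjects$group)), collapse = ", "),
    length(x$roi_ids), x$modality))
  invisible(x)
}

#' Write / read a cohort as a long CSV with a truth sidecar
#'
#' The on-disk layout is one row per subject x ROI x timepoint with
#' columns `subject_id, group, age, roi, lobe, modality, timepoint,
#' value, interval_days`; the generative truth (when present) is written
#' to `<path>.truth.json`.
#'
#' @param cohort A `cohort_table`.
#' @param path CSV path.
#' @return `write_cohort_csv()` returns `path` invisibly;
#'   `read_cohort_csv()` returns a `cohort_table` (without `params`).
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  lobes <- if (!is.null(cohort$lobe_map))
    as.character(cohort$lobe_map$lobe)[match(cohort$roi_ids,
                                             cohort$lobe_map$roi_id)]
  else rep(NA_character_, length(cohort$roi_ids))
  long <- do.call(rbind, lapply(c("baseline", "followup"), function(tp) {
    m <- cohort[[tp]]
    data.frame(
      subject_id = rep(cohort$subjects$subject_id, times = ncol(m)),
      group = rep(cohort$subjects$group, times = ncol(m)),
      age = rep(cohort$subjects$age_baseline, times = ncol(m)),
      roi = rep(cohort$roi_ids, each = nrow(m)),
      lobe = rep(lobes, each = nrow(m)),
      modality = cohort$modality,
      timepoint = tp,
      value = as.vector(m),
      interval_days = rep(cohort$subjects$interval_days, times = ncol(m)),
      stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(cohort$truth))
    jsonlite::write_json(
      lapply(cohort$truth, function(m) unclass(as.data.frame(m))),
      paste0(path, ".truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "age", "roi", "modality", "timepoint",
            "value", "interval_days")
  missing <- setdiff(need, names(long))
  if (length(missing))
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyNA(long[need]))
    stop("cohort CSV contains missing values", call. = FALSE)
  subj <- unique(long[, c("subject_id", "group", "age", "interval_days")])
  names(subj)[names(subj) == "age"] <- "age_baseline"
  rownames(subj) <- NULL
  roi_ids <- sort(unique(long$roi))
  to_matrix <- function(tp) {
    d <- long[long$timepoint == tp, ]
    m <- matrix(NA_real_, nrow(subj), length(roi_ids),
                dimnames = list(subj$subject_id, paste0("roi_", roi_ids)))
    m[cbind(match(d$subject_id, subj$subject_id),
            match(d$roi, roi_ids))] <- d$value
    if (anyNA(m)) {
      bad <- which(is.na(m), arr.ind = TRUE)
      stop("missing ", tp, " cells, e.g. subject ",
           subj$subject_id[bad[1, 1]], " ROI ", roi_ids[bad[1, 2]],
           call. = FALSE)
    }
    m
  }
  lobe_map <- if ("lobe" %in% names(long) && !anyNA(long$lobe)) {
    lm <- unique(long[, c("roi", "lobe")])
    data.frame(roi_id = lm$roi, lobe = lm$lobe, stringsAsFactors = FALSE)
  }
  structure(list(
    subjects = subj,
    baseline = to_matrix("baseline"),
    followup = to_matrix("followup"),
    modality = long$modality[1],
    roi_ids = roi_ids,
    lobe_map = lobe_map,
    params = NULL, truth = NULL
  ), class = "cohort_table")
}

#' Generate baseline/follow-up atlas phantoms with exact ROI medians
#'
#' Builds a pair of small 3D phantom volumes (tracer uptake, integer
#' atlas labels, grey-matter probability) in which every ROI's
#' tissue-masked median uptake equals a stated target exactly, so the
#' quantification stage can be tested against a construction oracle. Each
#' ROI occupies a contiguous block of voxels; an odd number survive the
#' grey-matter mask (their values straddle the target symmetrically, so
#' the sample median IS the target), and two low-probability voxels per
#' ROI carry outlying values that the mask must exclude. The reference
#' region (cerebellar crus grey matter) takes label `n_roi + 1`.
#'
#' @param n_roi Number of target ROIs.
#' @param roi_medians Length-`n_roi` vector of intended masked medians;
#'   if `NULL`, drawn uniformly on `(0.8, 2.5) * reference_median`.
#' @param reference_median Intended masked median of the reference
#'   region.
#' @param shape Length-3 integer volume shape; must host
#'   `n_roi + 1` disjoint blocks.
#' @param seed Seed for the randomized medians.
#' @param followup_scale Scalar or per-ROI factor applied to the ROI
#'   medians in the follow-up phantom (reference unchanged).
#' @param voxels_per_roi Voxels per ROI block (>= 9; 2 are masked out,
#'   leaving an odd count).
#' @return List with `baseline` and `followup` (each of class
#'   `atlas_phantom`: `uptake`, `labels`, `gm_probability` arrays plus a
#'   `truth` data frame of intended medians) and `reference_id`.
#' @export
#' @examples
#' ph <- generate_phantom(4, reference_median = 2, shape = c(10, 10, 4))
#' ph$baseline$truth
generate_phantom <- function(n_roi = 84L, roi_medians = NULL,
                             reference_median = 1,
                             shape = c(30L, 30L, 30L), seed = 1L,
                             followup_scale = 1.05,
                             voxels_per_roi = 27L) {
  stopifnot(length(shape) == 3L, voxels_per_roi >= 9L,
            reference_median > 0)
  set.seed(seed)
  if (is.null(roi_medians))
    roi_medians <- stats::runif(n_roi, 0.8, 2.5) * reference_median
  stopifnot(length(roi_medians) == n_roi, all(roi_medians > 0))
  followup_scale <- rep(followup_scale, length.out = n_roi)
  m <- as.integer(voxels_per_roi)
  n_blocks <- n_roi + 1L
  if (prod(shape) < n_blocks * m)
    stop(sprintf(
      "shape %s too small: %d voxels needed for %d blocks of %d",
      paste(shape, collapse = "x"), n_blocks * m, n_blocks, m),
      call. = FALSE)

  build <- function(targets, ref_target) {
    uptake <- array(0, dim = shape)
    labels <- array(0L, dim = shape)
    gm <- array(0, dim = shape)
    all_targets <- c(targets, ref_target)
    for (k in seq_len(n_blocks)) {
      idx <- ((k - 1L) * m + 1L):(k * m)
      labels[idx] <- if (k <= n_roi) k else reference_region_id(n_roi)
      # first 2 voxels: below-threshold GM, outlier uptake (mask test)
      gm[idx] <- c(0.1, 0.1, rep(0.9, m - 2L))
      kept <- m - 2L                      # odd by construction
      half <- (kept - 1L) / 2L
      spread <- 0.05 * all_targets[k]
      vals <- all_targets[k] + spread * seq(-half, half) / max(half, 1L)
      uptake[idx] <- c(rep(10 * all_targets[k], 2L), vals)
    }
    structure(list(
      uptake = uptake, labels = labels, gm_probability = gm,
      truth = data.frame(roi_id = seq_len(n_roi), median = targets)
    ), class = "atlas_phantom")
  }

  list(
    baseline = build(roi_medians, reference_median),
    followup = build(roi_medians * followup_scale, reference_median),
    reference_id = reference_region_id(n_roi)
  )
}

#' Write / read an atlas phantom as NIfTI volumes
#'
#' Writes `<prefix>_uptake.nii.gz`, `<prefix>_labels.nii.gz` and
#' `<prefix>_gm.nii.gz` under `dir`.
#'
#' @param phantom An `atlas_phantom`.
#' @param dir Output directory (created if needed).
#' @param prefix File prefix.
#' @return `write_phantom_nifti()` returns the three paths invisibly;
#'   `read_phantom_nifti()` returns an `atlas_phantom` (without truth).
#' @export
write_phantom_nifti <- function(phantom, dir, prefix = "phantom") {
  stopifnot(inherits(phantom, "atlas_phantom"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_uptake", "_labels", "_gm"),
                                 ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(phantom$uptake), paths[1],
                     datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(phantom$labels), paths[2],
                     datatype = "int32")
  RNifti::writeNifti(RNifti::asNifti(phantom$gm_probability), paths[3],
                     datatype = "double")
  invisible(paths)
}

#' @rdname write_phantom_nifti
#' @export
read_phantom_nifti <- function(dir, prefix = "phantom") {
  paths <- file.path(dir, paste0(prefix, c("_uptake", "_labels", "_gm"),
                                 ".nii.gz"))
  if (!all(file.exists(paths)))
    stop("phantom volumes not found under ", dir, call. = FALSE)
  structure(list(
    uptake = array(as.numeric(RNifti::readNifti(paths[1])),
                   dim = dim(RNifti::readNifti(paths[1]))),
    labels = array(as.integer(RNifti::readNifti(paths[2])),
                   dim = dim(RNifti::readNifti(paths[2]))),
    gm_probability = array(as.numeric(RNifti::readNifti(paths[3])),
                           dim = dim(RNifti::readNifti(paths[3]))),
    truth = NULL
  ), class = "atlas_phantom")
}
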