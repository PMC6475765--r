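#' Tissue-masked median uptake of one atlas ROI
#'
#' The ROI summary statistic used throughout: the median uptake over the
#' voxels carrying the ROI's atlas label whose grey-matter probability
#' exceeds the mask threshold. Masking on the segmentation keeps mostly
#' non-tissue voxels out of the median and thereby limits partial-volume
#' contamination without an explicit correction.
#'
#' @param uptake 3D numeric array (tracer counts, arbitrary units).
#' @param labels 3D integer array of atlas labels (0 = background).
#' @param gm_probability 3D numeric array in `[0, 1]`.
#' @param roi_id Atlas label to extract.
#' @param mask_threshold Voxels with `gm_probability > mask_threshold`
#'   enter the median (default 0.5).
#' @return The masked median uptake (scalar).
#' @export
#' @examples
#' u <- array(5, c(2, 2, 2)); l <- array(1L, c(2, 2, 2))
#' g <- array(0.9, c(2, 2, 2))
#' extract_roi_median(u, l, g, 1)
extract_roi_median <- function(uptake, labels, gm_probability, roi_id,
                               mask_threshold = 0.5) {
  stopifnot(identical(dim(uptake), dim(labels)),
            identical(dim(uptake), dim(gm_probability)))
  if (!any(labels == roi_id))
    stop("ROI ", roi_id, " absent from label volume", call. = FALSE)
  keep <- labels == roi_id & gm_probability > mask_threshold
  if (!any(keep))
    stop("no voxels of ROI ", roi_id, " survive the grey-matter mask (> ",
         mask_threshold, ")", call. = FALSE)
  stats::median(uptake[keep])
}

#' ROI medians for every label in a phantom
#'
#' Convenience wrapper applying [extract_roi_median()] to each ROI of an
#' `atlas_phantom` (or to explicit arrays).
#'
#' @param phantom An `atlas_phantom`.
#' @param roi_ids Labels to extract (default: all positive labels except
#'   `reference_id`).
#' @param reference_id Label of the reference region.
#' @param mask_threshold Grey-matter mask threshold.
#' @return List with `roi_medians` (named by ROI id) and
#'   `reference_median`.
#' @export
phantom_roi_medians <- function(phantom, roi_ids = NULL,
                                reference_id = NULL,
                                mask_threshold = 0.5) {
  labs <- sort(setdiff(unique(as.integer(phantom$labels)), 0L))
  if (is.null(reference_id)) reference_id <- max(labs)
  if (is.null(roi_ids)) roi_ids <- setdiff(labs, reference_id)
  med <- vapply(roi_ids, function(r)
    extract_roi_median(phantom$uptake, phantom$labels,
                       phantom$gm_probability, r, mask_threshold),
    numeric(1))
  names(med) <- roi_ids
  list(roi_medians = med,
       reference_median = extract_roi_median(
         phantom$uptake, phantom$labels, phantom$gm_probability,
         reference_id, mask_threshold))
}

#' Standard uptake value ratios from ROI medians
#'
#' Divides each ROI's median uptake by the median uptake of the reference
#' region (cerebellar crus grey matter), yielding dimensionless SUVRs;
#' the reference region itself has SUVR 1 by construction.
#'
#' @param roi_medians Named numeric vector of ROI median uptakes.
#' @param reference_median Median uptake of the reference region (> 0).
#' @param subject_id,timepoint Identifiers carried into the output.
#' @return A data frame (`subject_id`, `roi`, `timepoint`, `suvr`).
#' @export
#' @examples
#' compute_suvr(c(roi_1 = 2.84), reference_median = 2.0)
compute_suvr <- function(roi_medians, reference_median,
                         subject_id = NA_character_,
                         timepoint = c("baseline", "followup")) {
  if (!is.finite(reference_median) || reference_median <= 0)
    stop("invalid reference region: median must be > 0, got ",
         reference_median, call. = FALSE)
  timepoint <- match.arg(timepoint)
  data.frame(
    subject_id = subject_id,
    roi = if (is.null(names(roi_medians))) seq_along(roi_medians)
          else names(roi_medians),
    timepoint = timepoint,
    suvr = as.numeric(roi_medians) / reference_median,
    stringsAsFactors = FALSE
  )
}

#' Annualized SUVR change
#'
#' Follow-up minus baseline SUVR, divided by the scan interval expressed
#' in years (365.25 days); antisymmetric under swapping the timepoints.
#'
#' @param suvr_baseline,suvr_followup SUVR values (vectorized).
#' @param interval_days Scan interval in days (> 0).
#' @return Annualized change in SUVR/yr.
#' @export
#' @examples
#' annualized_suvr_change(1.0, 1.2, 365.25)  # 0.2 SUVR/yr
annualized_suvr_change <- function(suvr_baseline, suvr_followup,
                                   interval_days) {
  if (any(interval_days <= 0))
    stop("interval_days must be > 0", call. = FALSE)
  (suvr_followup - suvr_baseline) / (interval_days / 365.25)
}

#' Annualize a log-Jacobian value
#'
#' Divides the log of the deformation-field Jacobian determinant by the
#' number of days between scans and multiplies by 365.25, giving an
#' annualized log-Jacobian (approximately the annualized fractional
#' volume change for small deformations).
#'
#' @param log_jacobian Log-Jacobian value (vectorized).
#' @param interval_days Days between the scan pair (> 0).
#' @return Annualized log-Jacobian (per year).
#' @export
#' @examples
#' annualize_log_jacobian(-0.02, 730.5)  # -0.01 / yr
annualize_log_jacobian <- function(log_jacobian, interval_days) {
  if (any(interval_days <= 0))
    stop("interval_days must be > 0", call. = FALSE)
  log_jacobian / interval_days * 365.25
}

#' Normalize an ROI volume by total intracranial volume
#'
#' @param roi_volume ROI grey-matter volume (mm^3).
#' @param total_intracranial_volume Subject's TIV (mm^3, > 0).
#' @return Dimensionless volume fraction.
#' @export
#' @examples
#' normalize_roi_volume(1500, 1.5e6)  # 0.001
normalize_roi_volume <- function(roi_volume, total_intracranial_volume) {
  if (any(total_intracranial_volume <= 0))
    stop("total intracranial volume must be > 0", call. = FALSE)
  roi_volume / total_intracranial_volume
}

#' Amyloid positivity from a global SUVR
#'
#' Applies the global amyloid-PET cut-point; the boundary is inclusive
#' (a value exactly at the cut-point is called positive).
#'
#' @param global_suvr Global amyloid SUVR (> 0, vectorized).
#' @param cutpoint Positivity cut-point (default 1.42).
#' @return Character vector, `"positive"` or `"negative"`.
#' @export
#' @examples
#' classify_amyloid(c(2.49, 1.0, 1.42))
classify_amyloid <- function(global_suvr, cutpoint = 1.42) {
  if (any(global_suvr <= 0))
    stop("global_suvr must be > 0", call. = FALSE)
  ifelse(global_suvr >= cutpoint, "positive", "negative")
}

#' Annualized changes for every cell of a cohort
#'
#' Applies [annualized_suvr_change()] (the same arithmetic serves
#' volume-percent values) to each subject x ROI pair of a
#' `cohort_table`, returning the long table consumed by the modelling
#' stage.
#'
#' @param cohort A `cohort_table`.
#' @return A data frame (`subject_id`, `roi`, `modality`, `change`) plus
#'   attribute `change_matrix` (subjects x ROI).
#' @export
compute_annualized_changes <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  ch <- annualized_suvr_change(cohort$baseline, cohort$followup,
                               cohort$subjects$interval_days)
  out <- data.frame(
    subject_id = rep(cohort$subjects$subject_id, times = ncol(ch)),
    roi = rep(cohort$roi_ids, each = nrow(ch)),
    modality = cohort$modality,
    change = as.vector(ch),
    stringsAsFactors = FALSE
  )
  attr(out, "change_matrix") <- ch
  out
}
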