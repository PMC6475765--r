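#' Default ROI-to-lobe assignment
#'
#' Returns the packaged atlas convention: 84 cortical/subcortical
#' grey-matter regions of interest (42 per hemisphere) grouped into the
#' eight lobes used throughout the longitudinal analyses. The assignment is
#' a documented convention modelled on standard adult-lifespan-template
#' parcellations; studies using a different atlas can supply their own map
#' anywhere a `lobe_map` argument is accepted.
#'
#' @return A data frame with one row per ROI and columns `roi_id` (integer
#'   1..84), `roi_name`, `hemisphere` (`"left"`/`"right"`) and `lobe` (one
#'   of [lobe_levels()]).
#' @seealso [lobe_levels()], [reference_region_id()]
#' @export
#' @examples
#' map <- default_lobe_map()
#' table(map$lobe)
default_lobe_map <- function() {
  regions <- list(
    frontal = c(
      "superior frontal", "middle frontal", "inferior frontal opercular",
      "inferior frontal triangular", "inferior frontal orbital",
      "medial orbitofrontal", "lateral orbitofrontal", "gyrus rectus",
      "supplementary motor area", "anterior cingulate", "middle cingulate",
      "frontal pole"),
    sensorimotor = c(
      "precentral", "postcentral", "paracentral lobule",
      "rolandic operculum"),
    `medial temporal` = c(
      "hippocampus", "parahippocampal", "amygdala", "entorhinal"),
    `lateral temporal` = c(
      "superior temporal", "middle temporal", "inferior temporal",
      "temporal pole", "fusiform", "heschl"),
    `medial parietal` = c(
      "precuneus", "posterior cingulate", "isthmus cingulate",
      "retrosplenial"),
    `lateral parietal` = c(
      "superior parietal", "inferior parietal", "angular",
      "supramarginal"),
    `medial occipital` = c(
      "calcarine", "cuneus", "lingual", "medial occipitotemporal"),
    `lateral occipital` = c(
      "superior occipital", "middle occipital", "inferior occipital",
      "lateral occipitotemporal")
  )
  stopifnot(identical(names(regions), lobe_levels()))
  uni <- data.frame(
    roi_name = unlist(regions, use.names = FALSE),
    lobe = rep(names(regions), lengths(regions)),
    stringsAsFactors = FALSE
  )
  out <- rbind(
    transform(uni, hemisphere = "left"),
    transform(uni, hemisphere = "right")
  )
  out$roi_id <- seq_len(nrow(out))
  out$roi_name <- paste(out$hemisphere, out$roi_name)
  out$lobe <- factor(out$lobe, levels = lobe_levels())
  out[, c("roi_id", "roi_name", "hemisphere", "lobe")]
}

#' Lobe labels in display order
#'
#' The eight lobes, in the order used for the lobe-comparison matrix rows
#' and columns.
#'
#' @return Character vector of length 8.
#' @export
lobe_levels <- function() {
  c("frontal", "sensorimotor", "medial temporal", "lateral temporal",
    "medial parietal", "lateral parietal", "medial occipital",
    "lateral occipital")
}

#' Atlas label id of the SUVR reference region
#'
#' Label used for cerebellar crus grey matter in phantom volumes; ROI
#' labels run 1..`n_roi` and the reference region sits at `n_roi + 1`.
#'
#' @param n_roi Number of target ROIs (default 84).
#' @return Integer label id.
#' @export
reference_region_id <- function(n_roi = 84L) as.integer(n_roi) + 1L

#' Validate an ROI-to-lobe map
#'
#' @param lobe_map Data frame with columns `roi_id` and `lobe`.
#' @param n_roi Expected number of ROIs.
#' @return The map, invisibly, with `lobe` coerced to character.
#' @keywords internal
validate_lobe_map <- function(lobe_map, n_roi = NULL) {
  stopifnot(is.data.frame(lobe_map),
            all(c("roi_id", "lobe") %in% names(lobe_map)))
  if (anyDuplicated(lobe_map$roi_id) > 0L)
    stop("lobe map assigns some ROI more than once", call. = FALSE)
  if (!is.null(n_roi) && nrow(lobe_map) != n_roi)
    stop(sprintf("lobe map covers %d ROIs, expected %d",
                 nrow(lobe_map), n_roi), call. = FALSE)
  lobe_map$lobe <- as.character(lobe_map$lobe)
  invisible(lobe_map)
}
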