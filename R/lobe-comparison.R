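#' Lobe-wise average of regional contrast draws
#'
#' Per posterior draw, the unweighted mean of the contrast draws over the
#' member ROIs of each lobe.
#'
#' @param contrast_draws `chain x draw x roi` array (or draws x roi
#'   matrix) of regional contrast draws.
#' @param lobe_map ROI-to-lobe assignment (`roi_id`, `lobe`); defaults to
#'   [default_lobe_map()].
#' @param roi_ids ROI ids matching the third dimension of
#'   `contrast_draws` (default `lobe_map$roi_id` order 1..R).
#' @return A draws x lobe matrix (lobes in [lobe_levels()] order,
#'   restricted to lobes present in the map).
#' @export
lobe_average <- function(contrast_draws, lobe_map = default_lobe_map(),
                         roi_ids = NULL) {
  if (length(dim(contrast_draws)) == 3L) {
    d <- dim(contrast_draws)
    contrast_draws <- matrix(aperm(contrast_draws, c(2, 1, 3)),
                             d[1] * d[2], d[3])
  }
  lobe_map <- validate_lobe_map(lobe_map)
  roi_ids <- roi_ids %||% seq_len(ncol(contrast_draws))
  lobes <- lobe_map$lobe[match(roi_ids, lobe_map$roi_id)]
  if (anyNA(lobes))
    stop("ROI(s) ", paste(roi_ids[is.na(lobes)], collapse = ", "),
         " not assigned to any lobe", call. = FALSE)
  levels <- intersect(lobe_levels(), unique(lobes))
  empty <- setdiff(unique(lobe_map$lobe), lobes)
  if (length(empty))
    stop("lobe(s) with no member ROI: ", paste(empty, collapse = ", "),
         call. = FALSE)
  out <- sapply(levels, function(l)
    rowMeans(contrast_draws[, lobes == l, drop = FALSE]))
  colnames(out) <- levels
  out
}

#' Pairwise posterior lobe-comparison probabilities
#'
#' For every ordered lobe pair, the proportion of posterior draws in
#' which one lobe-wise average annualized change exceeds the other:
#' `p[row, col]` is the posterior probability that the *column* lobe has
#' a higher annualized change than the *row* lobe. Tied draws (measure
#' zero for continuous posteriors) are split half to each side, which
#' preserves the complement identity `p[i,j] + p[j,i] = 1` exactly.
#'
#' @param lobe_draws A draws x lobe matrix from [lobe_average()].
#' @return An object of class `lobe_comparison`: list with `p` (the
#'   lobe x lobe probability matrix, `NA` diagonal), `lobes` and
#'   `n_draws`.
#' @export
comparison_matrix <- function(lobe_draws) {
  stopifnot(is.matrix(lobe_draws), ncol(lobe_draws) >= 2L)
  if (nrow(lobe_draws) < 100L)
    warning("fewer than 100 draws: comparison probabilities are coarse",
            call. = FALSE)
  L <- ncol(lobe_draws)
  p <- matrix(NA_real_, L, L,
              dimnames = list(colnames(lobe_draws),
                              colnames(lobe_draws)))
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i == j) next
    diff <- lobe_draws[, j] - lobe_draws[, i]
    p[i, j] <- mean((diff > 0) + 0.5 * (diff == 0))
  }
  structure(list(p = p, lobes = colnames(lobe_draws),
                 n_draws = nrow(lobe_draws)),
            class = "lobe_comparison")
}

#' @export
print.lobe_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("<lobe_comparison> %d lobes, %d draws\n",
              length(x$lobes), x$n_draws))
  print(format_comparison(x), quote = FALSE)
  invisible(x)
}

#' Display-format a lobe-comparison matrix
#'
#' Formats probabilities with the conventional `<0.001` / `>0.999`
#' clipping used for published comparison tables; the raw values remain
#' in the `lobe_comparison` object.
#'
#' @param comparison A `lobe_comparison`.
#' @param digits Digits for the unclipped entries.
#' @return A character matrix.
#' @export
format_comparison <- function(comparison, digits = 3) {
  p <- comparison$p
  out <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  mid <- is.finite(p) & p >= 0.001 & p <= 0.999
  out[mid] <- formatC(p[mid], digits = digits, format = "f")
  out[is.finite(p) & p < 0.001] <- "<0.001"
  out[is.finite(p) & p > 0.999] <- ">0.999"
  out
}

#' Write a lobe-comparison matrix as CSV
#'
#' @param comparison A `lobe_comparison`.
#' @param path Output CSV path.
#' @param formatted Write the clipped display strings instead of raw
#'   probabilities.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path, formatted = FALSE) {
  m <- if (formatted) format_comparison(comparison) else comparison$p
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}
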