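#' Calibrate DAPI intensity against known DNA contents
#'
#' Fits the least-squares line of integrated DAPI intensity on known DNA
#' content using the two anchor populations: diakinesis-stage oocytes (4n)
#' and endoreduplicated intestine nuclei (32n). With only two distinct
#' anchor contents the fitted line interpolates both group mean intensities
#' exactly, so the inverse map returns the anchor contents at the anchor
#' means. Regression runs intensity-on-content (the contents are known, the
#' intensities noisy) and is inverted by [estimate_content()].
#'
#' @param measurements data frame with columns `population` and `intensity`.
#' @param anchors named numeric vector mapping anchor population names to
#'   DNA contents (default `c(oocyte_diakinesis = 4, intestine = 32)`).
#' @return A `PloidyCalibration`: list with `slope` (intensity per n),
#'   `intercept`, `anchors`, and `anchor_means`.
#' @export
calibrate_ploidy <- function(measurements,
                             anchors = c(oocyte_diakinesis = 4,
                                         intestine = 32)) {
  if (!all(c("population", "intensity") %in% names(measurements)))
    validation_error("measurements need 'population' and 'intensity' columns")
  if (length(anchors) < 2L)
    oc_abort("need at least two anchor populations",
             "oncochrom_calibration_error")
  present <- names(anchors) %in% measurements$population
  if (!all(present))
    oc_abort(sprintf("missing anchor population(s): %s",
                     paste(names(anchors)[!present], collapse = ", ")),
             "oncochrom_calibration_error")
  sel <- measurements$population %in% names(anchors)
  content <- unname(anchors[measurements$population[sel]])
  intensity <- measurements$intensity[sel]
  fit <- stats::lm.fit(cbind(1, content), intensity)
  slope <- unname(fit$coefficients[2])
  intercept <- unname(fit$coefficients[1])
  if (!is.finite(slope) || slope <= 0)
    oc_abort("calibration slope must be positive",
             "oncochrom_calibration_error")
  means <- vapply(names(anchors), function(p)
    mean(measurements$intensity[measurements$population == p]), 0)
  structure(list(slope = slope, intercept = intercept,
                 anchors = anchors, anchor_means = means),
            class = "PloidyCalibration")
}

#' Estimate DNA content from DAPI intensity
#'
#' Inverts the calibration line: `content = (intensity - intercept) / slope`.
#' Contents may exceed 32n (endomitotic nuclei accumulate DNA far beyond the
#' intestine anchor).
#'
#' @param intensity numeric intensities.
#' @param calibration a [calibrate_ploidy()] result.
#' @return Numeric DNA contents in n.
#' @export
estimate_content <- function(intensity, calibration) {
  stopifnot(inherits(calibration, "PloidyCalibration"))
  if (calibration$slope <= 0)
    oc_abort("non-positive calibration slope", "oncochrom_calibration_error")
  (intensity - calibration$intercept) / calibration$slope
}

#' Relative DNA content per nucleus population
#'
#' Content ratios versus the wild-type oocyte reference (4n by default),
#' summarized as boxplot-style statistics per population.
#'
#' @param contents data frame with columns `population` and `content`.
#' @param reference_content reference content in n (default 4).
#' @return Data frame per population: n, median, q25, q75 of
#'   `content / reference_content`; empty populations are dropped with a
#'   warning.
#' @export
relative_content_report <- function(contents, reference_content = 4) {
  if (!all(c("population", "content") %in% names(contents)))
    validation_error("contents need 'population' and 'content' columns")
  pops <- unique(contents$population)
  rows <- lapply(pops, function(p) {
    r <- contents$content[contents$population == p] / reference_content
    if (length(r) == 0L) {
      warning(sprintf("population %s is empty", p))
      return(NULL)
    }
    data.frame(population = p, n = length(r),
               median = stats::median(r),
               q25 = unname(stats::quantile(r, 0.25)),
               q75 = unname(stats::quantile(r, 0.75)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
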