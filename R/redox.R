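# Redox assays: Ellman glutathione arithmetic via a linear calibration
# curve, and relative H2O2 from DHE fluorescence.

#' Fit a GSH calibration curve
#'
#' Ordinary least-squares line `A415 = slope * concentration + intercept`
#' through the calibration points, with R-squared. A valid assay has a
#' positive slope; constant readings leave R-squared undefined and are
#' flagged.
#'
#' @param points data.frame with columns `concentration` and `value`
#'   (>= 3 distinct concentrations).
#' @return list with `slope`, `intercept`, `r_squared`, `flags`
#'   (character vector), `fit` (the `lm` object).
#' @export
fitCalibration <- function(points) {
  .stopIfNot(all(c("concentration", "value") %in% names(points)),
             "points needs 'concentration' and 'value' columns")
  conc <- points$concentration
  .stopIfNot(length(unique(conc)) >= 3,
             "need >= 3 distinct calibration concentrations")
  if (stats::sd(conc) == 0) stop("zero concentration spread", call. = FALSE)
  fit <- stats::lm(value ~ concentration, data = points)
  flags <- character(0)
  tss <- sum((points$value - mean(points$value))^2)
  if (tss > 0) {
    r2 <- 1 - sum(stats::residuals(fit)^2) / tss
  } else {
    r2 <- NA_real_
    flags <- c(flags, "constant_readings")
  }
  slope <- unname(stats::coef(fit)[2L])
  if (!is.na(slope) && slope <= 0) flags <- c(flags, "nonpositive_slope")
  list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
       r_squared = r2, flags = flags, fit = fit)
}

#' Glutathione concentrations from free and total reads
#'
#' Inverts the calibration curve for the free-GSH and post-reduction
#' (total) absorbance reads, then applies the Ellman arithmetic: each GSSG
#' reduces to two GSH, so `GSSG = (total - free) / 2`. Negative inverted
#' concentrations are clipped to 0 with a warning (plate-reader noise near
#' zero); `total < free` is flagged and GSSG clipped to 0.
#'
#' @param freeRead,totalRead absorbance values (A415).
#' @param curve calibration from [fitCalibration()] (slope must be > 0).
#' @return data.frame with columns `free_gsh`, `total_gsh`, `gssg`,
#'   `flagged` (logical).
#' @export
gshConcentrations <- function(freeRead, totalRead, curve) {
  .stopIfNot(is.finite(curve$slope) && curve$slope > 0,
             "calibration slope must be positive")
  inv <- function(a) (a - curve$intercept) / curve$slope
  freeC <- inv(freeRead)
  totC <- inv(totalRead)
  clip <- freeC < 0 | totC < 0
  if (any(clip)) {
    warning("negative back-calculated concentration(s) clipped to 0")
    freeC <- pmax(freeC, 0)
    totC <- pmax(totC, 0)
  }
  flagged <- totC < freeC
  if (any(flagged)) {
    warning("total GSH below free GSH; GSSG clipped to 0 and flagged")
  }
  gssg <- pmax((totC - freeC) / 2, 0)
  data.frame(free_gsh = freeC, total_gsh = totC, gssg = gssg,
             flagged = flagged | clip)
}

#' Process a full Ellman assay record set
#'
#' Convenience wrapper over [fitCalibration()] and [gshConcentrations()]
#' for the assay CSV dialect (`sample_id`, `reading_type` in
#' `free|total|calib`, `concentration`, `value`).
#'
#' @param readings assay data.frame (see [simulateAssayReadings()]).
#' @return data.frame with one row per sample: `sample_id`, `free_gsh`,
#'   `total_gsh`, `gssg`, `flagged`, plus calibration `slope`,
#'   `intercept`, `r_squared` repeated on each row.
#' @export
glutathioneAssay <- function(readings) {
  calib <- readings[readings$reading_type == "calib", , drop = FALSE]
  curve <- fitCalibration(calib)
  samples <- unique(readings$sample_id[readings$reading_type != "calib"])
  rows <- lapply(samples, function(sid) {
    fr <- readings$value[readings$sample_id == sid &
                           readings$reading_type == "free"]
    to <- readings$value[readings$sample_id == sid &
                           readings$reading_type == "total"]
    .stopIfNot(length(fr) == 1L && length(to) == 1L,
               paste("sample", sid, "needs exactly one free and one total read"))
    cbind(data.frame(sample_id = sid), gshConcentrations(fr, to, curve))
  })
  out <- do.call(rbind, rows)
  out$slope <- curve$slope
  out$intercept <- curve$intercept
  out$r_squared <- curve$r_squared
  out
}

#' Relative H2O2 from DHE fluorescence
#'
#' DHE fluorescence (ex 480 nm / em 625 nm) is an indirect, relative
#' readout: values are blank-corrected and expressed as the ratio to the
#' control-group mean. No absolute concentration is claimed.
#'
#' @param readings data.frame with columns `sample_id`, `group`, `value`.
#' @param blank blank fluorescence reading.
#' @param controlGroup name of the control group.
#' @return `readings` with added `corrected` (value - blank) and
#'   `ratio_to_control` columns.
#' @export
h2o2Relative <- function(readings, blank, controlGroup = "control") {
  .stopIfNot(!missing(blank) && is.finite(blank), "blank reading required")
  .stopIfNot(controlGroup %in% readings$group,
             paste("no readings for control group", controlGroup))
  readings$corrected <- readings$value - blank
  ctrl <- mean(readings$corrected[readings$group == controlGroup])
  readings$ratio_to_control <- readings$corrected / ctrl
  readings
}

#' Read / write assay CSV files
#' @param path file path.
#' @return `readAssay`: the readings data.frame.
#' @export
readAssay <- function(path) {
  d <- utils::read.csv(path)
  need <- c("sample_id", "reading_type", "concentration", "value")
  .stopIfNot(all(need %in% names(d)),
             paste("assay file needs columns:", paste(need, collapse = ", ")))
  d
}

#' @rdname readAssay
#' @param readings assay data.frame.
#' @return `writeAssay`: `path`, invisibly.
#' @export
writeAssay <- function(readings, path) {
  utils::write.csv(readings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
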