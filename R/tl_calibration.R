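# TL value -> air kerma calibration, background subtraction, conversion.

#' Construct a table of TLD readings
#'
#' A reading is the numerically integrated glow curve ("TL value", photon
#' counts) of one LiF:Mg,Ti chip, together with where the chip sat: its
#' triplet (`group_id`), the physical phantom slice, and the organ that slice
#' belongs to. Background/control chips conventionally carry `slice = NA` and
#' `organ = "background"`.
#'
#' @param chip_id,group_id Character labels.
#' @param slice Integer slice indices (NA for control chips).
#' @param organ Organ labels.
#' @param tl_value Non-negative TL integrals (counts).
#' @return A `tld_readings` data frame with those five columns.
#' @export
tld_readings <- function(chip_id, group_id, slice, organ, tl_value) {
  tl_value <- as.numeric(tl_value)
  if (any(tl_value < 0)) stop("tl_value must be >= 0", call. = FALSE)
  structure(
    data.frame(chip_id = as.character(chip_id),
               group_id = as.character(group_id),
               slice = as.integer(slice),
               organ = as.character(organ),
               tl_value = tl_value),
    class = c("tld_readings", "data.frame")
  )
}

#' Read TLD readings from CSV
#'
#' Expects columns `chip_id,group_id,slice,organ,tl_value`.
#'
#' @param path CSV path.
#' @return A [tld_readings()] data frame.
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) stop("readings file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chip_id", "group_id", "slice", "organ", "tl_value")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("readings CSV '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tld_readings(d$chip_id, d$group_id, d$slice, d$organ, d$tl_value)
}

#' Write TLD readings to CSV
#' @param readings A [tld_readings()] data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_readings <- function(readings, path) {
  utils::write.csv(as.data.frame(readings), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read calibration points from CSV
#'
#' Expects columns `tl_value,kerma_mGy,kerma_sigma_mGy`; each row is one
#' calibration exposure (a TL integral read out against the air kerma
#' measured by a calibrated ion chamber).
#'
#' @param path CSV path.
#' @return Data frame with columns `tl_value`, `kerma`, `kerma_sigma`.
#' @export
read_calibration_points <- function(path) {
  if (!file.exists(path)) {
    stop("calibration file not found: ", path, call. = FALSE)
  }
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tl_value", "kerma_mGy", "kerma_sigma_mGy")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("calibration CSV '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  calibration_points(d$tl_value, d$kerma_mGy, d$kerma_sigma_mGy)
}

#' Construct calibration points
#' @param tl_value TL integrals (counts).
#' @param kerma Measured air kerma (mGy), >= 0.
#' @param kerma_sigma Standard uncertainty of `kerma` (mGy), >= 0.
#' @return Data frame with columns `tl_value`, `kerma`, `kerma_sigma`.
#' @export
calibration_points <- function(tl_value, kerma, kerma_sigma = 0) {
  kerma <- as.numeric(kerma)
  kerma_sigma <- rep_len(as.numeric(kerma_sigma), length(kerma))
  if (any(kerma < 0) || any(kerma_sigma < 0)) {
    stop("kerma and kerma_sigma must be >= 0", call. = FALSE)
  }
  data.frame(tl_value = as.numeric(tl_value), kerma = kerma,
             kerma_sigma = kerma_sigma)
}

#' Construct a calibration curve
#'
#' The straight-line mapping `K_air = slope * TL + intercept` for one beam
#' quality, with parameter standard uncertainties and their covariance.
#'
#' @param slope Slope in mGy per count (> 0).
#' @param intercept Intercept in mGy.
#' @param slope_sigma,intercept_sigma Parameter standard uncertainties.
#' @param cov Covariance of slope and intercept (defaults to 0).
#' @param beam_quality Label such as `"RQT9"`, `"CT-120kV"`, `"CT-80kV"`.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(slope, intercept = 0, slope_sigma = 0,
                              intercept_sigma = 0, cov = 0,
                              beam_quality = "unspecified") {
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be finite and > 0 (got ", slope,
         "); negative or zero slopes signal corrupted input", call. = FALSE)
  }
  structure(
    list(slope = as.numeric(slope), intercept = as.numeric(intercept),
         slope_sigma = as.numeric(slope_sigma),
         intercept_sigma = as.numeric(intercept_sigma),
         cov = as.numeric(cov), beam_quality = as.character(beam_quality)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [%s]: K_air = %.6g * TL %s %.6g mGy\n",
              x$beam_quality, x$slope, if (x$intercept < 0) "-" else "+",
              abs(x$intercept)))
  cat(sprintf("  slope sigma %.3g, intercept sigma %.3g\n",
              x$slope_sigma, x$intercept_sigma))
  invisible(x)
}

#' Fit a TL-to-air-kerma calibration curve
#'
#' Fits `kerma ~ tl_value` by (weighted) least squares, minimising residuals
#' in kerma. Points with positive `kerma_sigma` are weighted by
#' `1/kerma_sigma^2`; if any sigma is zero or missing, ordinary least squares
#' is used. Parameter uncertainties come from the standard linear-regression
#' covariance matrix.
#'
#' @param points Data frame from [calibration_points()] or
#'   [read_calibration_points()].
#' @param force_zero_intercept If `TRUE`, fit `kerma = slope * tl_value`
#'   through the origin (a single point then suffices).
#' @param beam_quality Label stored on the returned curve.
#' @return A [calibration_curve()].
#' @examples
#' pts <- calibration_points(c(100, 200, 300), c(0.21, 0.39, 0.61))
#' fit_calibration(pts)  # slope 0.002, intercept 0.00333
#' @export
fit_calibration <- function(points, force_zero_intercept = FALSE,
                            beam_quality = "unspecified") {
  stopifnot(is.data.frame(points))
  n_min <- if (force_zero_intercept) 1L else 2L
  if (nrow(points) < n_min) {
    stop("need at least ", n_min, " calibration point(s)", call. = FALSE)
  }
  if (!force_zero_intercept && length(unique(points$tl_value)) < 2) {
    stop("degenerate calibration design: all TL values equal", call. = FALSE)
  }
  w <- if (all(points$kerma_sigma > 0)) 1 / points$kerma_sigma^2 else NULL

  if (force_zero_intercept && nrow(points) == 1L) {
    # exact ratio; no residual-based uncertainty available
    return(calibration_curve(points$kerma / points$tl_value,
                             beam_quality = beam_quality))
  }
  fml <- if (force_zero_intercept) kerma ~ tl_value + 0 else kerma ~ tl_value
  fit <- stats::lm(fml, data = points, weights = w)
  cf <- stats::coef(fit)
  # noise-free synthetic data produces an exactly perfect fit; the summary
  # warning about it is expected, and the zero covariance is correct
  V <- withCallingHandlers(
    stats::vcov(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  # with < 1 residual degree of freedom the covariance is undefined; fall
  # back to zero uncertainties (exact interpolation case)
  if (any(!is.finite(V))) V[] <- 0
  if (force_zero_intercept) {
    slope <- cf[["tl_value"]]
    if (slope <= 0) stop("fitted calibration slope is not positive (",
                         signif(slope, 4), ")", call. = FALSE)
    calibration_curve(slope, 0, sqrt(V["tl_value", "tl_value"]), 0, 0,
                      beam_quality)
  } else {
    slope <- cf[["tl_value"]]
    if (slope <= 0) stop("fitted calibration slope is not positive (",
                         signif(slope, 4), ")", call. = FALSE)
    calibration_curve(slope, cf[["(Intercept)"]],
                      sqrt(V["tl_value", "tl_value"]),
                      sqrt(V["(Intercept)", "(Intercept)"]),
                      V["tl_value", "(Intercept)"], beam_quality)
  }
}

#' Subtract the background (control group) TL signal
#'
#' One TLD group is left outside the examination room during each
#' irradiation; the arithmetic mean of its TL values estimates the background
#' accumulated between annealing and readout and is subtracted from every
#' exposed chip. Differences that would go negative are clamped to zero with
#' a warning.
#'
#' @param readings A [tld_readings()] data frame (exposed chips).
#' @param background_group A [tld_readings()] data frame (control chips), or
#'   a numeric vector of control TL values. Must be non-empty.
#' @return `readings` with `tl_value` background-subtracted.
#' @export
subtract_background <- function(readings, background_group) {
  bg <- if (is.data.frame(background_group)) background_group$tl_value
        else as.numeric(background_group)
  if (length(bg) == 0) stop("background group is empty", call. = FALSE)
  sub <- mean(bg)
  new_tl <- readings$tl_value - sub
  n_neg <- sum(new_tl < 0)
  if (n_neg > 0) {
    warning(n_neg, " reading(s) fell below the background mean (",
            signif(sub, 5), " counts) and were clamped to 0", call. = FALSE)
    new_tl <- pmax(new_tl, 0)
  }
  readings$tl_value <- new_tl
  readings
}

#' Convert TL values to air kerma
#'
#' Applies the calibration line `K = slope * TL + intercept` and propagates
#' the curve's parameter uncertainties to first order (the TL value is
#' treated as exact here; chip-to-chip scatter enters later through the
#' group variance in the inverse-variance slice weighting):
#' `var(K) = TL^2 s_slope^2 + s_int^2 + 2 TL cov(slope, int)`.
#'
#' @param tl Numeric vector of (background-subtracted) TL values, or a
#'   [tld_readings()] data frame.
#' @param curve A [calibration_curve()].
#' @return Data frame with columns `kerma` (mGy) and `variance` (mGy^2);
#'   when `tl` is a readings data frame the columns are appended to it.
#' @export
tl_to_kerma <- function(tl, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  is_df <- is.data.frame(tl)
  tlv <- if (is_df) tl$tl_value else as.numeric(tl)
  kerma <- curve$slope * tlv + curve$intercept
  variance <- tlv^2 * curve$slope_sigma^2 + curve$intercept_sigma^2 +
    2 * tlv * curve$cov
  variance <- pmax(variance, 0)  # guard tiny negative from covariance
  if (is_df) {
    tl$kerma <- kerma
    tl$variance <- variance
    tl
  } else {
    data.frame(kerma = kerma, variance = variance)
  }
}
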