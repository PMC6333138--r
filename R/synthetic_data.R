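# Seeded synthetic TLD data: readings with the statistical structure the
# pipeline assumes, calibration exposure sets, and qualitative TCM profiles.

#' Construct a noise model for synthetic TLD data
#'
#' The generator applies multiplicative Gaussian noise to TL values —
#' the usual picture of LiF:Mg,Ti batch response scatter. Published organ
#' dose tables show roughly 5% relative uncertainties, so `chip_cv`
#' defaults to 0.05; the remaining magnitudes are design choices, not
#' measured facts.
#'
#' @param chip_cv Per-chip fractional coefficient of variation (>= 0).
#' @param background_tl Mean background TL signal (counts, >= 0).
#' @param background_cv Fractional CV of the background signal.
#' @param calib_cv Fractional CV of calibration kerma measurements.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(chip_cv = 0.05, background_tl = 100,
                        background_cv = 0.05, calib_cv = 0.02, seed = 1L) {
  stopifnot(chip_cv >= 0, background_cv >= 0, calib_cv >= 0,
            background_tl >= 0)
  structure(list(chip_cv = chip_cv, background_tl = background_tl,
                 background_cv = background_cv, calib_cv = calib_cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Construct a truth scenario
#'
#' Fixes everything the generator needs to fabricate a consistent data set:
#' the phantom layout, the protocol, the true per-slice organ doses, and the
#' calibration curve the synthetic TL values are expressed against. Truth
#' doses are inputs, not computed from beam physics.
#'
#' @param layout A [phantom_layout()].
#' @param protocol A [protocol_config()].
#' @param true_slice_doses Named list (by organ) of named numeric vectors
#'   mapping slice index to true dose (mGy); a single unnamed number per
#'   organ is recycled over that organ's slices (flat truth).
#' @param curve A [calibration_curve()].
#' @return An object of class `truth_scenario`.
#' @export
truth_scenario <- function(layout, protocol, true_slice_doses, curve) {
  stopifnot(inherits(layout, "phantom_layout"),
            inherits(protocol, "protocol_config"),
            inherits(curve, "calibration_curve"))
  organs <- names(layout$fraction_tables)
  if (!all(organs %in% names(true_slice_doses))) {
    stop("true_slice_doses must name every layout organ: ",
         paste(organs, collapse = ", "), call. = FALSE)
  }
  doses <- list()
  for (org in organs) {
    slices <- layout$fraction_tables[[org]]$slice
    d <- true_slice_doses[[org]]
    if (length(d) == 1 && is.null(names(d))) {
      d <- stats::setNames(rep(d, length(slices)), slices)
    }
    missing <- setdiff(as.character(slices), names(d))
    if (length(missing)) {
      stop("organ '", org, "': no truth dose for slice(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    doses[[org]] <- d[as.character(slices)]
  }
  structure(list(layout = layout, protocol = protocol,
                 true_slice_doses = doses, curve = curve),
            class = "truth_scenario")
}

#' Expected whole-organ truth doses of a scenario
#'
#' Mass-fraction weighted sums of the scenario's true slice doses — the
#' values a perfect pipeline should recover.
#'
#' @param scenario A [truth_scenario()].
#' @return Named numeric vector, one dose (mGy) per organ.
#' @export
truth_organ_doses <- function(scenario) {
  vapply(names(scenario$layout$fraction_tables), function(org) {
    t <- scenario$layout$fraction_tables[[org]]
    sum(t$f * as.numeric(scenario$true_slice_doses[[org]]))
  }, 1)
}

#' Generate synthetic TLD readings
#'
#' Inverts the estimation chain: for each slice the true dose is converted
#' to air kerma through the organ/air coefficient ratio, then to a noiseless
#' TL value through the calibration curve; each chip gets multiplicative
#' Gaussian noise `(1 + e)`, `e ~ N(0, chip_cv)`, plus the background
#' signal. Exactly `n_groups` triplets of chips are produced per slice, and
#' one 3-chip control group records background only. Deterministic under the
#' noise model's seed.
#'
#' @param scenario A [truth_scenario()].
#' @param noise A [noise_model()].
#' @param chips_per_group Chips per TLD group (default 3).
#' @return List with `readings` (exposed [tld_readings()]), `background`
#'   (control [tld_readings()]) and `truth` (scenario truth record:
#'   per-organ doses and generation parameters).
#' @export
generate_readings <- function(scenario, noise, chips_per_group = 3L) {
  stopifnot(inherits(scenario, "truth_scenario"),
            inherits(noise, "noise_model"))
  curve <- scenario$curve
  tube_voltage <- scenario$protocol$tube_voltage

  withr::with_seed(noise$seed, {
    rows <- list()
    g_counter <- 0L
    for (org in names(scenario$layout$fraction_tables)) {
      tab <- scenario$layout$fraction_tables[[org]]
      coeffs <- mass_energy_coefficients(org, tube_voltage)
      for (i in seq_len(nrow(tab))) {
        sl <- tab$slice[i]
        d_true <- as.numeric(scenario$true_slice_doses[[org]][as.character(sl)])
        kerma_true <- d_true / coeffs$ratio
        tl_true <- (kerma_true - curve$intercept) / curve$slope
        for (g in seq_len(tab$n_groups[i])) {
          g_counter <- g_counter + 1L
          gid <- sprintf("G%03d", g_counter)
          eps <- stats::rnorm(chips_per_group, 0, noise$chip_cv)
          tl <- tl_true * (1 + eps) + noise$background_tl
          rows[[length(rows) + 1L]] <- tld_readings(
            chip_id = sprintf("%s-c%d", gid, seq_len(chips_per_group)),
            group_id = gid, slice = sl, organ = org,
            tl_value = pmax(tl, 0))
        }
      }
    }
    eps_bg <- stats::rnorm(chips_per_group, 0, noise$background_cv)
    background <- tld_readings(
      chip_id = sprintf("BG-c%d", seq_len(chips_per_group)),
      group_id = "BG", slice = NA_integer_, organ = "background",
      tl_value = pmax(noise$background_tl * (1 + eps_bg), 0))
    readings <- do.call(rbind, rows)
  })
  class(readings) <- c("tld_readings", "data.frame")
  list(readings = readings, background = background,
       truth = list(organ_doses = as.list(truth_organ_doses(scenario)),
                    slice_doses = lapply(scenario$true_slice_doses, as.list),
                    tube_voltage = tube_voltage,
                    curve = unclass(curve), noise = unclass(noise)))
}

#' Generate a synthetic calibration exposure set
#'
#' TL values span a range and the paired kerma follows the given curve,
#' perturbed multiplicatively by `calib_cv`; `kerma_sigma` is recorded as
#' `calib_cv` times the noiseless kerma (zero `calib_cv` yields exact
#' points with zero sigma).
#'
#' @param curve A [calibration_curve()] to emulate.
#' @param n_points Number of exposures, >= 2.
#' @param noise A [noise_model()] (uses `calib_cv` and `seed`).
#' @param tl_range TL span of the exposures (counts).
#' @return A [calibration_points()] data frame.
#' @export
generate_calibration_set <- function(curve, n_points, noise,
                                     tl_range = c(500, 10000)) {
  stopifnot(inherits(curve, "calibration_curve"),
            inherits(noise, "noise_model"))
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  tl <- seq(tl_range[1], tl_range[2], length.out = n_points)
  k_true <- curve$slope * tl + curve$intercept
  withr::with_seed(noise$seed, {
    k <- k_true * (1 + stats::rnorm(n_points, 0, noise$calib_cv))
  })
  calibration_points(tl, pmax(k, 0), noise$calib_cv * k_true)
}

#' Generate a qualitative longitudinal TCM profile
#'
#' Emulates the contrast seen between patients and phantoms under
#' longitudinal tube current modulation in chest scans: patient profiles
#' start high at the neck (arms raised, dense shoulders) and decrease toward
#' the lungs; phantom profiles start low at the neck and increase toward the
#' lungs. A smooth half-cosine ramp spans the neck-to-lung range and is
#' clipped to the protocol's mA bounds. No attenuation physics is modelled.
#'
#' @param positions Longitudinal table positions (mm), neck at the minimum.
#' @param base_mA Level used for the `"constant"` anatomy.
#' @param anatomy `"phantom"`, `"patient"` or `"constant"`.
#' @param bounds `(min, max)` mA clip range, e.g. a protocol's TCM range.
#' @return List with `positions`, `mA` and `mean_mA`.
#' @export
generate_tcm_profile <- function(positions, base_mA,
                                 anatomy = c("phantom", "patient",
                                             "constant"),
                                 bounds = NULL) {
  anatomy <- match.arg(anatomy)
  positions <- as.numeric(positions)
  if (!is.null(bounds)) {
    if (length(bounds) != 2 || bounds[1] > bounds[2]) {
      stop("bounds must be (min, max) with min <= max", call. = FALSE)
    }
  }
  if (anatomy == "constant") {
    mA <- rep(base_mA, length(positions))
  } else {
    span <- range(positions)
    s <- if (diff(span) > 0) (positions - span[1]) / diff(span) else
      rep(0, length(positions))
    lo <- if (is.null(bounds)) 0.5 * base_mA else bounds[1]
    hi <- if (is.null(bounds)) 1.5 * base_mA else bounds[2]
    ramp <- (1 - cos(pi * s)) / 2  # 0 at the neck, 1 at the far end
    mA <- if (anatomy == "phantom") lo + (hi - lo) * ramp
          else hi - (hi - lo) * ramp
  }
  if (!is.null(bounds)) mA <- pmin(pmax(mA, bounds[1]), bounds[2])
  list(positions = positions, mA = mA, mean_mA = mean(mA))
}

#' Write a complete synthetic data set to disk
#'
#' Emits everything a pipeline run needs: readings CSV, background CSV,
#' calibration CSV, layout JSON, protocol JSON and a truth JSON for test
#' harnesses. Used by the `synth` CLI subcommand.
#'
#' @param scenario A [truth_scenario()].
#' @param noise A [noise_model()].
#' @param out_dir Output directory (created if absent).
#' @param n_calibration Calibration exposures to generate.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_dataset <- function(scenario, noise, out_dir,
                                    n_calibration = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_readings(scenario, noise)
  cal <- generate_calibration_set(scenario$curve, n_calibration, noise)
  paths <- c(
    readings = file.path(out_dir, "readings.csv"),
    background = file.path(out_dir, "background.csv"),
    calibration = file.path(out_dir, "calibration.csv"),
    layout = file.path(out_dir, "layout.json"),
    protocol = file.path(out_dir, "protocol.json"),
    truth = file.path(out_dir, "truth.json"))
  write_readings(gen$readings, paths[["readings"]])
  write_readings(gen$background, paths[["background"]])
  utils::write.csv(
    data.frame(tl_value = cal$tl_value, kerma_mGy = cal$kerma,
               kerma_sigma_mGy = cal$kerma_sigma),
    paths[["calibration"]], row.names = FALSE, quote = FALSE)
  write_layout(scenario$layout, paths[["layout"]])
  p <- scenario$protocol
  jsonlite::write_json(
    list(phantom_id = scenario$layout$phantom_id,
         protocols = list(list(
           name = p$name, tube_voltage = p$tube_voltage,
           tube_current = p$tube_current, rotation_time = p$rotation_time,
           pitch = p$pitch, collimation = p$collimation,
           ctdi_vol = p$ctdi_vol, dlp = p$dlp, tcm_mode = p$tcm_mode))),
    paths[["protocol"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(gen$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
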