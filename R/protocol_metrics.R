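# Protocol-level dosimetric quantities: mAs, effective mAs, normalized dose
# metrics, percent reductions, and CTDIvol-coefficient organ-dose estimates.

#' Construct a protocol configuration
#'
#' Holds the acquisition parameters of one CT protocol together with the
#' console dose indices. `tube_current` is a single mA value for
#' fixed-current protocols or a `(min, max)` pair for tube current
#' modulation (TCM).
#'
#' @param name Protocol label.
#' @param tube_voltage Tube voltage (kV).
#' @param tube_current mA (length 1) or mA range (length 2, min <= max).
#' @param rotation_time Gantry rotation time (s), > 0.
#' @param pitch Helical pitch, > 0.
#' @param collimation Collimation label, e.g. `"64x0.625"`.
#' @param ctdi_vol Console CTDIvol (mGy), >= 0.
#' @param dlp Console dose-length product (mGy cm), >= 0.
#' @param tcm_mode `"none"`, `"longitudinal"` or `"longitudinal+angular"`.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(name, tube_voltage, tube_current, rotation_time,
                            pitch, collimation = NA_character_,
                            ctdi_vol = NA_real_, dlp = NA_real_,
                            tcm_mode = c("none", "longitudinal",
                                         "longitudinal+angular")) {
  tcm_mode <- match.arg(tcm_mode)
  tube_current <- as.numeric(tube_current)
  stopifnot(length(tube_current) %in% 1:2, pitch > 0, rotation_time > 0)
  if (length(tube_current) == 2 && tube_current[1] > tube_current[2]) {
    stop("tube current range must be (min, max)", call. = FALSE)
  }
  if (length(tube_current) == 2 && tcm_mode == "none") {
    stop("a tube current range requires a TCM mode", call. = FALSE)
  }
  if (!is.na(ctdi_vol) && ctdi_vol < 0) stop("ctdi_vol must be >= 0",
                                             call. = FALSE)
  structure(
    list(name = name, tube_voltage = tube_voltage,
         tube_current = tube_current, rotation_time = rotation_time,
         pitch = pitch, collimation = collimation, ctdi_vol = ctdi_vol,
         dlp = dlp, tcm_mode = tcm_mode),
    class = "protocol_config"
  )
}

#' @export
print.protocol_config <- function(x, ...) {
  cur <- if (length(x$tube_current) == 2) {
    sprintf("%g-%g mA (%s TCM)", x$tube_current[1], x$tube_current[2],
            x$tcm_mode)
  } else sprintf("%g mA", x$tube_current)
  cat(sprintf("Protocol %s: %g kV, %s, %gs rotation, pitch %g, CTDIvol %s mGy\n",
              x$name, x$tube_voltage, cur, x$rotation_time, x$pitch,
              format(x$ctdi_vol)), sep = "")
  invisible(x)
}

#' Load protocol configurations from JSON
#'
#' Reads `{"phantom_id": ..., "protocols": [...]}` files; the packaged
#' fixtures `protocols_adult.json` and `protocols_pediatric.json` transcribe
#' the GE adult and Philips pediatric chest protocol sets studied here.
#'
#' @param path JSON path.
#' @return Named list of [protocol_config()] objects.
#' @export
load_protocols <- function(path) {
  if (!file.exists(path)) stop("protocol file not found: ", path,
                               call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$protocols)) {
    stop("protocol file '", path, "' is missing field 'protocols'",
         call. = FALSE)
  }
  out <- lapply(doc$protocols, function(p) {
    protocol_config(p$name, p$tube_voltage, unlist(p$tube_current),
                    p$rotation_time, p$pitch,
                    collimation = p$collimation %||% NA_character_,
                    ctdi_vol = p$ctdi_vol %||% NA_real_,
                    dlp = p$dlp %||% NA_real_,
                    tcm_mode = p$tcm_mode %||% "none")
  })
  names(out) <- vapply(doc$protocols, `[[`, "", "name")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tube current-time product (mAs)
#'
#' `tube_current * rotation_time` for a fixed-current protocol. TCM
#' protocols have no single mAs; computing one from a modulation profile is
#' the role of [generate_tcm_profile()]'s mean current.
#'
#' @param protocol A [protocol_config()].
#' @return mAs (numeric).
#' @export
tube_mAs <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_config"))
  if (length(protocol$tube_current) != 1) {
    stop("protocol '", protocol$name, "' uses TCM; there is no fixed mAs. ",
         "Use the mean current of a modulation profile instead.",
         call. = FALSE)
  }
  protocol$tube_current * protocol$rotation_time
}

#' Effective mAs
#'
#' The helical-scan normalisation `mAs_eff = mAs / pitch`.
#'
#' @param mAs_value Tube current-time product (mAs).
#' @param pitch Helical pitch, > 0.
#' @return mAs_eff (numeric).
#' @export
effective_mAs <- function(mAs_value, pitch) {
  if (any(pitch <= 0)) stop("pitch must be > 0", call. = FALSE)
  mAs_value / pitch
}

#' Dose normalised by (effective) mAs
#'
#' @param dose Organ dose (mGy).
#' @param protocol A fixed-current [protocol_config()].
#' @param effective If `TRUE`, divide by `mAs / pitch` instead of mAs.
#' @param sigma Optional dose standard uncertainty; scaled by the same
#'   denominator.
#' @param mAs_override Use this mAs instead of the protocol product (the
#'   published pediatric tables use the display-rounded values 55 and
#'   146 mAs, not the full-precision products 54.45 and 145.35).
#' @return List with `value` (mGy/mAs or mGy/mAs_eff) and `sigma`.
#' @export
dose_per_mAs <- function(dose, protocol, effective = FALSE, sigma = 0,
                         mAs_override = NULL) {
  m <- if (is.null(mAs_override)) tube_mAs(protocol) else mAs_override
  denom <- if (effective) effective_mAs(m, protocol$pitch) else m
  list(value = dose / denom, sigma = sigma / denom)
}

#' Percent dose decrease between two protocols
#'
#' `(reference - new) / reference * 100`, positive when the new protocol
#' lowers the dose; the k = 1 uncertainty is first-order propagation of both
#' dose sigmas (doses treated as independent).
#'
#' @param reference_dose,new_dose Doses (mGy); `reference_dose` > 0.
#' @param reference_sigma,new_sigma Dose standard uncertainties (mGy).
#' @return List with `value` (percent) and `sigma`.
#' @examples
#' percent_decrease(14.30, 3.88)$value  # 72.9
#' @export
percent_decrease <- function(reference_dose, new_dose,
                             reference_sigma = 0, new_sigma = 0) {
  if (any(reference_dose <= 0)) stop("reference dose must be > 0",
                                     call. = FALSE)
  value <- (reference_dose - new_dose) / reference_dose * 100
  sigma <- 100 * sqrt((new_sigma / reference_dose)^2 +
                        (new_dose * reference_sigma / reference_dose^2)^2)
  list(value = value, sigma = sigma)
}

#' Scout (SPR) dose as a fraction of a protocol dose
#'
#' The scan projection radiograph acquired before the CT scan deposits a
#' small dose; this expresses it as a percentage of the dose from a full
#' protocol.
#'
#' @param spr_dose SPR organ dose (mGy), >= 0.
#' @param protocol_dose Protocol organ dose (mGy), > 0.
#' @return Percent (numeric).
#' @export
spr_fraction <- function(spr_dose, protocol_dose) {
  if (any(protocol_dose <= 0)) stop("protocol dose must be > 0",
                                    call. = FALSE)
  spr_dose / protocol_dose * 100
}

#' Construct an organ-dose coefficient
#'
#' A scanner-independent coefficient `f_organ` relating organ dose to
#' CTDIvol for a reference-size patient at a given tube voltage (e.g.
#' `f_lung = 1.50 +/- 0.06` at 120 kV for a 70 kg adult chest).
#'
#' @param organ,tube_voltage Labels the coefficient is valid for.
#' @param f_organ Coefficient (> 0), dimensionless (mGy per mGy CTDIvol).
#' @param f_sigma Its standard uncertainty.
#' @return An object of class `organ_coefficient`.
#' @export
organ_coefficient <- function(organ, tube_voltage, f_organ, f_sigma = 0) {
  if (f_organ <= 0) stop("f_organ must be > 0", call. = FALSE)
  structure(list(organ = organ, tube_voltage = tube_voltage,
                 f_organ = f_organ, f_sigma = f_sigma),
            class = "organ_coefficient")
}

#' Load packaged organ-dose coefficients
#'
#' @param organ,tube_voltage Selection keys.
#' @param path Optional CSV override with columns
#'   `organ,tube_voltage,f_organ,f_sigma`.
#' @return An [organ_coefficient()].
#' @export
load_organ_coefficient <- function(organ, tube_voltage, path = NULL) {
  tab <- utils::read.csv(
    if (is.null(path)) ctdose_extdata("organ_coefficients.csv") else path,
    stringsAsFactors = FALSE)
  row <- tab[tab$organ == organ & tab$tube_voltage == tube_voltage, ]
  if (nrow(row) != 1) {
    stop("no organ coefficient for '", organ, "' at ", tube_voltage, " kV",
         call. = FALSE)
  }
  organ_coefficient(organ, tube_voltage, row$f_organ, row$f_sigma)
}

#' CTDIvol-based organ dose estimate
#'
#' The console-index shortcut `dose = f_organ * CTDIvol`, with
#' `sigma = f_sigma * CTDIvol` (the console CTDIvol is treated as exact).
#'
#' @param coef An [organ_coefficient()].
#' @param protocol A [protocol_config()] whose tube voltage must match the
#'   coefficient's.
#' @return List with `value` (mGy) and `sigma`.
#' @examples
#' ped <- organ_coefficient("lung", 120, 1.50, 0.06)
#' @export
ctdi_based_dose <- function(coef, protocol) {
  stopifnot(inherits(coef, "organ_coefficient"),
            inherits(protocol, "protocol_config"))
  if (coef$tube_voltage != protocol$tube_voltage) {
    stop("coefficient is for ", coef$tube_voltage, " kV but protocol '",
         protocol$name, "' uses ", protocol$tube_voltage, " kV",
         call. = FALSE)
  }
  list(value = coef$f_organ * protocol$ctdi_vol,
       sigma = coef$f_sigma * protocol$ctdi_vol)
}

#' Relative difference between CTDIvol-based and TLD dose estimates
#'
#' `(ctdi_dose - tld_dose) / ctdi_dose * 100`, positive when the
#' CTDIvol-based estimate exceeds the TLD measurement; uncertainty by
#' first-order propagation of both sigmas.
#'
#' @param tld_dose,ctdi_dose Doses (mGy); `ctdi_dose` > 0.
#' @param tld_sigma,ctdi_sigma Standard uncertainties.
#' @return List with `value` (percent) and `sigma`.
#' @export
relative_difference <- function(tld_dose, ctdi_dose, tld_sigma = 0,
                                ctdi_sigma = 0) {
  if (any(ctdi_dose <= 0)) stop("ctdi_dose must be > 0", call. = FALSE)
  value <- (ctdi_dose - tld_dose) / ctdi_dose * 100
  sigma <- 100 * sqrt((tld_sigma / ctdi_dose)^2 +
                        (tld_dose * ctdi_sigma / ctdi_dose^2)^2)
  list(value = value, sigma = sigma)
}
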