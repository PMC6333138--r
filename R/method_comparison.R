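# Agreement between TLD-measured and Monte Carlo simulated organ doses:
# per-pair percent differences and Bland-Altman limits of agreement.

#' Construct dose pairs for method comparison
#'
#' Each pair holds one experimentally measured organ dose (`d_exp`, with its
#' k = 1 uncertainty) and the corresponding simulated reference dose
#' (`d_sim`, treated as exact since reference calculators report no
#' uncertainty).
#'
#' @param label Protocol/organ labels.
#' @param d_exp Measured doses (mGy).
#' @param d_sim Simulated doses (mGy), all > 0.
#' @param d_exp_sigma Measured-dose standard uncertainties (mGy).
#' @return A `dose_pairs` data frame.
#' @export
dose_pairs <- function(label, d_exp, d_sim, d_exp_sigma = 0) {
  d_sim <- as.numeric(d_sim)
  if (any(d_sim <= 0)) stop("d_sim must be > 0", call. = FALSE)
  structure(
    data.frame(label = as.character(label), d_exp = as.numeric(d_exp),
               d_exp_sigma = rep_len(as.numeric(d_exp_sigma), length(d_exp)),
               d_sim = d_sim),
    class = c("dose_pairs", "data.frame")
  )
}

#' Read comparison dose pairs from CSV
#'
#' Expects columns `label,d_exp_mGy,d_exp_sigma,d_sim_mGy`; the packaged
#' fixture `ncict_comparison_adult.csv` carries the five adult chest
#' protocol pairs.
#'
#' @param path CSV path.
#' @return A [dose_pairs()] data frame.
#' @export
read_dose_pairs <- function(path) {
  if (!file.exists(path)) stop("comparison file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "d_exp_mGy", "d_exp_sigma", "d_sim_mGy")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("comparison CSV '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  dose_pairs(d$label, d$d_exp_mGy, d$d_sim_mGy, d$d_exp_sigma)
}

#' Percent difference between simulated and measured dose
#'
#' `Delta = (d_sim - d_exp) / d_sim * 100`; positive when the simulation
#' exceeds the measurement. The uncertainty is `d_exp_sigma / d_sim * 100`
#' (the simulated dose is treated as exact).
#'
#' @param d_exp Measured dose (mGy).
#' @param d_sim Simulated dose (mGy), > 0.
#' @param d_exp_sigma Measured-dose standard uncertainty.
#' @return List with `value` (percent) and `sigma`.
#' @examples
#' percent_difference(14.30, 13.24)$value  # -8.0
#' @export
percent_difference <- function(d_exp, d_sim, d_exp_sigma = 0) {
  if (any(d_sim <= 0)) stop("d_sim must be > 0", call. = FALSE)
  list(value = (d_sim - d_exp) / d_sim * 100,
       sigma = d_exp_sigma / d_sim * 100)
}

#' Bland-Altman agreement analysis on percent differences
#'
#' Computes the per-pair percent differences, their mean (the bias), the
#' sample (n - 1) standard deviation, and the 95% limits of agreement
#' `bias +/- 1.96 * SD`, together with the pair means
#' `(d_sim + d_exp) / 2` used as the plot abscissa.
#'
#' @param pairs A [dose_pairs()] data frame with at least two rows.
#' @return An object of class `agreement_result` with fields `delta`
#'   (percent differences), `bias`, `sd`, `loa_low`, `loa_high`,
#'   `mean_axis`, `n` and the input `pairs`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "data.frame"))
  if (nrow(pairs) < 2) {
    stop("Bland-Altman needs at least 2 pairs (SD undefined otherwise)",
         call. = FALSE)
  }
  delta <- percent_difference(pairs$d_exp, pairs$d_sim)$value
  bias <- mean(delta)
  s <- stats::sd(delta)
  structure(
    list(delta = delta, bias = bias, sd = s,
         loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
         mean_axis = (pairs$d_sim + pairs$d_exp) / 2,
         n = nrow(pairs), pairs = pairs),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Bland-Altman agreement over %d pairs\n", x$n))
  cat(sprintf("  bias %.1f%%, SD %.1f%%, 95%% limits of agreement [%.1f, %.1f]%%\n",
              x$bias, x$sd, x$loa_low, x$loa_high))
  invisible(x)
}

#' Check percent differences against an agreement band
#'
#' Flags every |Delta| against a symmetric band (the study criterion used
#' here is 20%) and reports the largest absolute difference.
#'
#' @param result An [bland_altman()] result, or a numeric vector of percent
#'   differences.
#' @param band Half-width of the band in percent, > 0 (default 20).
#' @return List with `band`, `pass` (all within band), `max_abs_delta`,
#'   and a data frame `detail` (`delta`, `within`).
#' @export
within_band <- function(result, band = 20) {
  if (band <= 0) stop("band must be > 0", call. = FALSE)
  delta <- if (inherits(result, "agreement_result")) result$delta
           else as.numeric(result)
  within <- abs(delta) <= band
  list(band = band, pass = all(within), max_abs_delta = max(abs(delta)),
       detail = data.frame(delta = delta, within = within))
}

#' Bland-Altman plot
#'
#' Draws percent differences against pair means with the bias (solid) and
#' 95% limits of agreement (dashed) as horizontal lines.
#'
#' @param result An [bland_altman()] result.
#' @param file Optional output file; a device is chosen by extension
#'   (`.pdf` or `.png`).
#' @param ... Passed to [graphics::plot()].
#' @return `result`, invisibly.
#' @export
plot_bland_altman <- function(result, file = NULL, ...) {
  stopifnot(inherits(result, "agreement_result"))
  if (!is.null(file)) {
    ext <- tolower(sub(".*\\.", "", file))
    switch(ext,
           pdf = grDevices::pdf(file, width = 6, height = 4.5),
           png = grDevices::png(file, width = 720, height = 540),
           stop("unsupported plot format: .", ext, call. = FALSE))
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(result$mean_axis, result$delta,
                 xlab = "Mean dose (D_sim + D_exp)/2 [mGy]",
                 ylab = expression(Delta ~ "[%]"),
                 ylim = range(c(result$delta, result$loa_low,
                                result$loa_high)),
                 pch = 19, ...)
  graphics::abline(h = result$bias, col = "blue")
  graphics::abline(h = c(result$loa_low, result$loa_high), lty = 2)
  invisible(result)
}
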