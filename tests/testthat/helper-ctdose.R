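# Shared builders for the test suite. All synthetic inputs are generated in
# code; fixtures on disk are limited to the packaged extdata tables.

test_curve <- function(slope = 0.002, intercept = 0, ...) {
  calibration_curve(slope, intercept, beam_quality = "test", ...)
}

adult_layout <- function() load_layout(ctdose_extdata("adult_rando.json"))
pediatric_layout <- function() load_layout(ctdose_extdata("pediatric_cirs.json"))

adult_protocols <- function() load_protocols(ctdose_extdata("protocols_adult.json"))
pediatric_protocols <- function() load_protocols(ctdose_extdata("protocols_pediatric.json"))

measured_doses <- function() {
  utils::read.csv(ctdose_extdata("measured_doses.csv"),
                  stringsAsFactors = FALSE)
}

get_dose <- function(doses, protocol, organ) {
  row <- doses[doses$protocol == protocol & doses$organ == organ, ]
  stopifnot(nrow(row) == 1)
  list(dose = row$dose_mGy, sigma = row$sigma_mGy)
}

# agreement with a published value at its printed precision:
# |actual - printed| <= half a unit in the last printed digit
expect_printed <- function(actual, printed, digits) {
  expect_lte(abs(actual - printed), 0.5 * 10^(-digits) + 1e-12)
}

# tiny two-slice layout for fast pipeline tests
mini_layout <- function() {
  phantom_layout("mini", list(
    lung = organ_fraction_table("mini", "lung", slice = c(1L, 2L),
                                f = c(0.4, 0.6), n_groups = c(2L, 3L),
                                sum_tol = 1e-9)))
}

flat_scenario <- function(layout, dose, protocol, curve = test_curve()) {
  truths <- stats::setNames(
    rep(list(dose), length(layout$fraction_tables)),
    names(layout$fraction_tables))
  truth_scenario(layout, protocol, truths, curve)
}
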