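test_that("generated readings reproduce the layout's group placements", {
  layout <- adult_layout()
  sc <- flat_scenario(layout, 14.30, adult_protocols()$STD)
  gen <- generate_readings(sc, noise_model(seed = 61))
  r <- gen$readings
  expect_equal(length(unique(r$group_id)), 40L)
  expect_equal(nrow(r), 40L * 3L)
  counts <- table(r$slice) / 3
  tab <- layout$fraction_tables$lung
  expect_equal(as.integer(counts[as.character(tab$slice)]), tab$n_groups)
  expect_equal(nrow(gen$background), 3L)
  expect_true(all(r$tl_value >= 0))

  ped <- pediatric_layout()
  scp <- flat_scenario(ped, 6, pediatric_protocols()$`CfC-120`)
  genp <- generate_readings(scp, noise_model(seed = 61))
  expect_equal(length(unique(genp$readings$group_id)), 36L)
  expect_equal(sum(genp$readings$organ == "thyroid"), 4L * 3L)
  expect_equal(sum(genp$readings$organ == "lung"), 32L * 3L)
})

test_that("generation is deterministic under a fixed seed", {
  sc <- flat_scenario(mini_layout(), 10, adult_protocols()$STD)
  g1 <- generate_readings(sc, noise_model(seed = 62))
  g2 <- generate_readings(sc, noise_model(seed = 62))
  expect_identical(g1$readings, g2$readings)
  expect_identical(g1$background, g2$background)
  g3 <- generate_readings(sc, noise_model(seed = 63))
  expect_false(identical(g1$readings$tl_value, g3$readings$tl_value))

  # byte-identical files on re-run
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_dataset(sc, noise_model(seed = 62), d1)
  write_synthetic_dataset(sc, noise_model(seed = 62), d2)
  for (f in c("readings.csv", "background.csv", "calibration.csv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("noise-free generation inverts the pipeline exactly", {
  for (bundle in list(list(adult_layout(), adult_protocols()$STD, 14.30, 120),
                      list(pediatric_layout(),
                           pediatric_protocols()$`CfC-80`, 4.58, 80))) {
    layout <- bundle[[1]]
    sc <- flat_scenario(layout, bundle[[3]], bundle[[2]])
    gen <- generate_readings(sc, noise_model(chip_cv = 0, background_tl = 0,
                                             background_cv = 0, seed = 1))
    res <- run_pipeline(gen$readings, gen$background, test_curve(), layout,
                        bundle[[4]])
    for (org in names(layout$fraction_tables)) {
      expect_equal(res[[org]]$dose, bundle[[3]], tolerance = 1e-9)
    }
  }
})

test_that("a non-flat truth map is recovered noise-free", {
  layout <- adult_layout()
  tab <- layout$fraction_tables$lung
  doses <- stats::setNames(seq(8, 16, length.out = nrow(tab)), tab$slice)
  sc <- truth_scenario(layout, adult_protocols()$STD, list(lung = doses),
                       test_curve())
  expected <- sum(tab$f * doses)
  expect_equal(truth_organ_doses(sc)[["lung"]], expected)
  gen <- generate_readings(sc, noise_model(chip_cv = 0, background_tl = 0,
                                           background_cv = 0, seed = 1))
  res <- run_pipeline(gen$readings, gen$background, test_curve(), layout, 120)
  expect_equal(res$lung$dose, expected, tolerance = 1e-9)
})

test_that("truth_scenario validates completeness of the dose map", {
  layout <- adult_layout()
  expect_error(truth_scenario(layout, adult_protocols()$STD,
                              list(thyroid = 5), test_curve()),
               "every layout organ")
  expect_error(truth_scenario(layout, adult_protocols()$STD,
                              list(lung = c(`11` = 5)), test_curve()),
               "no truth dose")
})

test_that("generate_calibration_set is exact at zero noise and seeded", {
  curve <- test_curve(slope = 0.0018, intercept = 0.02)
  pts <- generate_calibration_set(curve, 10,
                                  noise_model(calib_cv = 0, seed = 64))
  fit <- fit_calibration(pts)
  expect_equal(fit$slope, curve$slope, tolerance = 1e-12)
  expect_equal(fit$intercept, curve$intercept, tolerance = 1e-10)
  expect_error(generate_calibration_set(curve, 1, noise_model()), ">= 2")

  p1 <- generate_calibration_set(curve, 10, noise_model(seed = 65))
  p2 <- generate_calibration_set(curve, 10, noise_model(seed = 65))
  expect_identical(p1, p2)
})

test_that("calibration slope recovery is unbiased at 2% noise", {
  curve <- test_curve()
  slopes <- vapply(1:500, function(s) {
    pts <- generate_calibration_set(curve, 10,
                                    noise_model(calib_cv = 0.02, seed = s))
    fit_calibration(pts)$slope
  }, 1)
  expect_lt(abs(mean(slopes) - curve$slope) / curve$slope, 0.005)
})

test_that("TCM profiles emulate the patient/phantom contrast", {
  z <- seq(0, 300, by = 10)  # neck at 0
  flat <- generate_tcm_profile(z, 100, "constant")
  expect_true(all(flat$mA == 100))

  ph <- generate_tcm_profile(z, 100, "phantom", bounds = c(66, 118))
  expect_true(all(ph$mA >= 66 & ph$mA <= 118))
  pt <- generate_tcm_profile(z, 100, "patient", bounds = c(66, 118))
  # opposite slopes over the neck-to-lung span: phantom rises, patient falls
  half <- seq_len(length(z) %/% 2)
  expect_gt(mean(diff(ph$mA[half])), 0)
  expect_lt(mean(diff(pt$mA[half])), 0)
  expect_equal(ph$mean_mA, mean(ph$mA))

  expect_error(generate_tcm_profile(z, 100, "phantom", bounds = c(118, 66)),
               "min, max")
})

test_that("write_synthetic_dataset emits a loadable, consistent bundle", {
  layout <- adult_layout()
  sc <- flat_scenario(layout, 14.30, adult_protocols()$STD)
  out <- withr::local_tempdir()
  paths <- write_synthetic_dataset(sc, noise_model(chip_cv = 0,
                                                   background_tl = 0,
                                                   background_cv = 0,
                                                   calib_cv = 0,
                                                   seed = 66), out)
  expect_true(all(file.exists(paths)))
  readings <- read_readings(paths[["readings"]])
  background <- read_readings(paths[["background"]])
  curve <- fit_calibration(read_calibration_points(paths[["calibration"]]))
  layout2 <- load_layout(paths[["layout"]])
  res <- run_pipeline(readings, background, curve, layout2, 120)
  expect_equal(res$lung$dose, 14.30, tolerance = 1e-6)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(truth$organ_doses[["lung"]], 14.30, tolerance = 1e-9)
})
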