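test_that("group_stats computes mean and unbiased variance with a floor", {
  # hand oracle: var(0.9, 1.0, 1.1) = (0.01 + 0 + 0.01) / 2 = 0.01
  g <- group_stats(c(0.9, 1.0, 1.1))
  expect_equal(g$mean_kerma, 1.0)
  expect_equal(g$variance, 0.01)
  expect_false(g$floored)

  ident <- group_stats(c(1.0, 1.0, 1.0))
  expect_true(ident$floored)
  expect_equal(ident$variance, (0.01 * 1.0)^2)  # default 1% floor

  single <- group_stats(2.0)
  expect_equal(single$mean_kerma, 2.0)
  expect_true(single$floored)
  expect_equal(single$variance, (0.01 * 2.0)^2)

  expect_error(group_stats(numeric(0)), "empty")
})

test_that("slice_weighted_kerma implements the inverse-variance mean", {
  mk <- function(k, v, slice = 1L) {
    structure(list(group_id = "g", slice = slice, mean_kerma = k,
                   variance = v, n_chips = 3L, floored = FALSE),
              class = "group_kerma_stat")
  }
  # hand oracle: (1.0/0.01 + 2.0/0.04) / (1/0.01 + 1/0.04) = 150/125 = 1.2
  sk <- slice_weighted_kerma(list(mk(1.0, 0.01), mk(2.0, 0.04)))
  expect_equal(sk$kerma, 1.2)
  expect_equal(sk$variance, 1 / 125)

  # equal variances -> arithmetic mean
  ks <- c(3.1, 2.9, 3.4)
  sk2 <- slice_weighted_kerma(lapply(ks, mk, v = 0.02))
  expect_equal(sk2$kerma, mean(ks))

  # single group passes through
  sk3 <- slice_weighted_kerma(list(mk(2.5, 0.03)))
  expect_equal(sk3$kerma, 2.5)
  expect_equal(sk3$variance, 0.03)

  expect_error(slice_weighted_kerma(list()), "no TLD groups")
  expect_error(slice_weighted_kerma(list(mk(1, 0.01, 1L), mk(1, 0.01, 2L))),
               "multiple slices")
})

test_that("weighted-mean properties hold on random inputs", {
  mk <- function(k, v) {
    structure(list(group_id = "g", slice = 1L, mean_kerma = k, variance = v,
                   n_chips = 3L, floored = FALSE),
              class = "group_kerma_stat")
  }
  withr::with_seed(21, {
    for (i in 1:50) {
      G <- sample(2:6, 1)
      k <- runif(G, 0.5, 20)
      v <- runif(G, 1e-4, 0.5)
      sk <- slice_weighted_kerma(mapply(mk, k, v, SIMPLIFY = FALSE))
      # brute-force direct summation oracle (independent of the package path)
      num <- 0; den <- 0
      for (n in seq_len(G)) {
        num <- num + k[n] / v[n]
        den <- den + 1 / v[n]
      }
      expect_equal(sk$kerma, num / den, tolerance = 1e-12)
      # convexity: within [min, max] of group means
      expect_gte(sk$kerma, min(k) - 1e-12)
      expect_lte(sk$kerma, max(k) + 1e-12)
      # equal-variance limit: algebraic identity with the arithmetic mean
      ve <- rep(v[1], G)
      ske <- slice_weighted_kerma(mapply(mk, k, ve, SIMPLIFY = FALSE))
      expect_equal(ske$kerma, mean(k), tolerance = 1e-12)
      # permutation invariance
      p <- sample(G)
      skp <- slice_weighted_kerma(mapply(mk, k[p], v[p], SIMPLIFY = FALSE))
      expect_equal(skp$kerma, sk$kerma, tolerance = 1e-12)
      expect_equal(skp$variance, sk$variance, tolerance = 1e-12)
    }
  })
})

test_that("slice_dose applies the coefficient ratio from the packaged table", {
  sk <- list(slice = 1L, kerma = 10, variance = 0.04)
  lung120 <- mass_energy_coefficients("lung", 120)
  d <- slice_dose(sk, lung120)
  expect_equal(d$dose, 10 * 0.0365 / 0.0339)   # 10.767 mGy
  expect_equal(d$dose, 10.767, tolerance = 1e-4)
  expect_equal(d$variance, 0.04 * (0.0365 / 0.0339)^2)

  thy80 <- mass_energy_coefficients("thyroid", 80)
  expect_equal(slice_dose(sk, thy80)$dose, 10 * 0.0610 / 0.0521)  # 11.708
  expect_equal(slice_dose(sk, thy80)$dose, 11.708, tolerance = 1e-4)

  expect_equal(slice_dose(list(slice = 1L, kerma = 0, variance = 0),
                          lung120)$dose, 0)
  expect_error(slice_dose(sk, lung120, organ = "thyroid"), "organ")
  expect_error(slice_dose(sk, lung120, tube_voltage = 80), "kV")
  expect_error(mass_energy_coefficients("liver", 120), "no mass-energy")
})

test_that("organ_dose mass-fraction weighting matches its oracle", {
  frac <- organ_fraction_table("p", "lung", 1:2, c(0.4, 0.6), c(1, 1),
                               sum_tol = 1e-9)
  sd_ <- function(slice, dose, var = 0) list(slice = slice, dose = dose,
                                             variance = var)
  res <- organ_dose(list(sd_(1L, 10), sd_(2L, 20)), frac)
  expect_equal(res$dose, 16.0)

  # uniform dose on any valid table returns that dose (sum f = 1)
  t3 <- adult_layout()$fraction_tables$lung
  uni <- organ_dose(lapply(t3$slice, sd_, dose = 7.7), t3)
  expect_equal(uni$dose, 7.7, tolerance = 1e-12)

  # random doses vs an independent brute-force summation oracle
  withr::with_seed(22, {
    for (i in 1:20) {
      d <- runif(nrow(t3), 1, 30)
      v <- runif(nrow(t3), 0, 0.1)
      res2 <- organ_dose(mapply(sd_, t3$slice, d, v, SIMPLIFY = FALSE), t3)
      acc <- 0; vacc <- 0
      for (j in seq_len(nrow(t3))) {
        acc <- acc + t3$f[j] * d[j]
        vacc <- vacc + t3$f[j]^2 * v[j]
      }
      expect_equal(res2$dose, acc, tolerance = 1e-12)
      expect_equal(res2$sigma, sqrt(vacc), tolerance = 1e-12)
      # result is self-consistent with its own per_slice record
      expect_equal(res2$dose, sum(res2$per_slice$f * res2$per_slice$dose),
                   tolerance = 1e-12)
    }
  })

  expect_error(organ_dose(list(sd_(1L, 10)), frac), "slice\\(s\\) 2")
})

test_that("run_pipeline recovers a noise-free flat truth exactly", {
  layout <- adult_layout()
  sc <- flat_scenario(layout, 14.30, adult_protocols()$STD)
  gen <- generate_readings(sc, noise_model(chip_cv = 0, background_tl = 0,
                                           background_cv = 0, seed = 1))
  res <- run_pipeline(gen$readings, gen$background, test_curve(), layout, 120)
  expect_equal(res$lung$dose, 14.30, tolerance = 1e-12)
})

test_that("pipeline linearity: doubling chip kermas doubles dose and sigma", {
  layout <- mini_layout()
  proto <- adult_protocols()$STD
  sc <- flat_scenario(layout, 10, proto)
  gen <- generate_readings(sc, noise_model(chip_cv = 0.05, background_tl = 0,
                                           seed = 31))
  curve1 <- test_curve(slope = 0.002)
  curve2 <- test_curve(slope = 0.004)  # doubles every chip kerma
  r1 <- run_pipeline(gen$readings, gen$background, curve1, layout, 120)
  r2 <- run_pipeline(gen$readings, gen$background, curve2, layout, 120)
  expect_equal(r2$lung$dose, 2 * r1$lung$dose, tolerance = 1e-10)
  expect_equal(r2$lung$sigma, 2 * r1$lung$sigma, tolerance = 1e-10)
})

test_that("pipeline is invariant under permutation of reading rows", {
  layout <- mini_layout()
  sc <- flat_scenario(layout, 5, adult_protocols()$LD)
  gen <- generate_readings(sc, noise_model(seed = 32))
  r1 <- run_pipeline(gen$readings, gen$background, test_curve(), layout, 120)
  withr::with_seed(33, perm <- sample(nrow(gen$readings)))
  shuffled <- gen$readings[perm, ]
  r2 <- run_pipeline(shuffled, gen$background, test_curve(), layout, 120)
  expect_equal(r2$lung$dose, r1$lung$dose, tolerance = 1e-12)
  expect_equal(r2$lung$sigma, r1$lung$sigma, tolerance = 1e-12)
})

test_that("run_pipeline names missing slices in its error", {
  layout <- adult_layout()
  sc <- flat_scenario(layout, 14.30, adult_protocols()$STD)
  gen <- generate_readings(sc, noise_model(seed = 34))
  partial <- gen$readings[gen$readings$slice != 15L, ]
  expect_error(
    run_pipeline(partial, gen$background, test_curve(), layout, 120),
    "slice\\(s\\) 15")
})
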