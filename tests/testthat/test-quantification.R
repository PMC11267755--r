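test_that("envelope summation reproduces constructed fixtures exactly", {
  # single peak, K = 0
  one <- peaklist(1334.60, 250)
  es <- envelope_sum(one, 1334.60, K = 0)
  expect_equal(es$total_intensity, 250)
  expect_false(es$absent)

  # 5-peak envelope of known intensities
  spacing <- mass_constants()$isotope_spacing
  ints <- c(100, 80, 40, 15, 5)
  env <- peaklist(1334.60 + (0:4) * spacing, ints)
  expect_equal(envelope_sum(env, 1334.60, K = 4)$total_intensity, sum(ints))
  # missing isotopologues contribute zero
  expect_equal(envelope_sum(env, 1334.60, K = 10)$total_intensity, sum(ints))

  # RDA companion at fraction 0.3 of the main envelope
  both <- peaklist(c(1334.60 + (0:4) * spacing, 1031.47 + (0:4) * spacing),
                   c(ints, 0.3 * ints))
  expect_equal(envelope_sum(both, 1334.60, K = 4, rda = TRUE)$total_intensity,
               1.3 * sum(ints))

  # absent species
  expect_true(envelope_sum(one, 1500, K = 2)$absent)
})

test_that("intensity ratios behave as constructed", {
  spacing <- mass_constants()$isotope_spacing
  ints <- c(100, 80, 40)
  obs <- peaklist(c(1320.58 + (0:2) * spacing, 1334.60 + (0:2) * spacing),
                  c(ints, ints))
  expect_equal(intensity_ratio(obs, 1320.58, 1334.60, K = 2), 1.0)

  obs2 <- peaklist(c(1320.58 + (0:2) * spacing, 1334.60 + (0:2) * spacing),
                   c(0.25 * ints, ints))
  expect_equal(intensity_ratio(obs2, 1320.58, 1334.60, K = 2), 0.25)
  # scale invariance
  obs3 <- peaklist(obs2$mz, 7.3 * obs2$intensity)
  expect_equal(intensity_ratio(obs3, 1320.58, 1334.60, K = 2), 0.25)
  # denominator absent
  expect_error(intensity_ratio(obs2, 1320.58, 1600, K = 2), "absent")
})

test_that("equal RDA fractions leave the ratio unchanged; unequal change it", {
  sim_pair <- function(frac_a, frac_b) {
    spacing <- mass_constants()$isotope_spacing
    ints <- c(100, 60, 20)
    peaklist(
      c(1320.58 + (0:2) * spacing, 1320.58 - 303.13 + (0:2) * spacing,
        1334.60 + (0:2) * spacing, 1334.60 - 303.13 + (0:2) * spacing),
      c(0.4 * ints, 0.4 * frac_a * ints, ints, frac_b * ints))
  }
  eq <- sim_pair(0.3, 0.3)
  expect_equal(intensity_ratio(eq, 1320.58, 1334.60, K = 2, rda = TRUE),
               intensity_ratio(eq, 1320.58, 1334.60, K = 2, rda = FALSE))
  ne <- sim_pair(0.5, 0.2)
  expect_gt(intensity_ratio(ne, 1320.58, 1334.60, K = 2, rda = TRUE),
            intensity_ratio(ne, 1320.58, 1334.60, K = 2, rda = FALSE))
})

test_that("response-factor fits recover exact and noisy calibrations", {
  known <- c(0.25, 0.5, 1, 2)
  exact <- fit_response(known, 0.8 * known)
  expect_equal(exact$slope, 0.8)
  expect_equal(exact$intercept, 0, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1)

  noisy <- withr::with_seed(42,
    fit_response(titration_ratios,
                 0.8 * titration_ratios * (1 + 0.05 * rnorm(5))))
  expect_gte(noisy$r_squared, 0.99)

  origin <- fit_response(known, 0.8 * known + 0.1, through_origin = TRUE)
  expect_equal(origin$intercept, 0)

  expect_error(fit_response(1, 1), "at least 2")
  expect_error(fit_response(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("tidy and glance expose the calibration", {
  fit <- fit_response(c(0.25, 0.5, 1), 0.8 * c(0.25, 0.5, 1) + c(1, -1, 1) * 0.01)
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "known"))
  gl <- glance(fit)
  expect_equal(gl$slope, fit$slope)
  expect_equal(gl$r.squared, fit$r_squared)
  expect_equal(gl$n, 3L)
})

test_that("ratio estimation inverts the calibration line", {
  id <- fit_response(c(0.5, 1, 2), c(0.5, 1, 2))
  expect_equal(estimate_ratio(id, 0.7), 0.7)
  f <- fit_response(c(0.5, 1, 2), 0.8 * c(0.5, 1, 2))
  expect_equal(estimate_ratio(f, 0.2), 0.25)
  zero <- f; zero$slope <- 0
  expect_error(estimate_ratio(zero, 0.2), "zero")
})

test_that("a simulated mixing ratio is recovered through the full titration", {
  tt <- gen_titration(titration_ratios, 0.8, M_SER, M_THR,
                      rda_fraction = 0.3, intensity_cv = 0.05, seed = 7)
  measured <- vapply(tt$peaklist, function(pl)
    intensity_ratio(pl, ion_mz(M_SER), ion_mz(M_THR), rda = TRUE), numeric(1))
  fit <- fit_response(tt$known_ratio, measured)
  mix <- gen_peaklist(
    tibble::tibble(label = c("A", "B"), mass = c(M_SER, M_THR),
                   abundance = c(0.25 * 0.8 * 1000, 1000)),
    rda_fraction = 0.3, intensity_cv = 0.05, seed = 19)
  est <- estimate_ratio(fit, intensity_ratio(mix, ion_mz(M_SER), ion_mz(M_THR),
                                             rda = TRUE))
  expect_lt(abs(est - 0.25) / 0.25, 0.10)
})

test_that("Beer-Lambert quantification is linear in absorbance", {
  expect_equal(pvd_concentration(0), 0)
  expect_equal(pvd_concentration(0.19), 1.0e-5)
  expect_equal(pvd_concentration(1.9), 1.0e-4)
  expect_equal(pvd_concentration(0.19, path = 2), 0.5e-5)
  expect_error(pvd_concentration(-0.1), ">= 0")
})

test_that("titration series quantify from files with a JSON report", {
  dir <- withr::local_tempdir()
  tt <- gen_titration(c(0.25, 0.5, 1), 0.8, M_SER, M_THR,
                      rda_fraction = 0.3, seed = 3)
  files <- sprintf("pl_%d.csv", seq_len(nrow(tt)))
  purrr::walk2(tt$peaklist, files, function(pl, f)
    write_peaklist_csv(pl, file.path(dir, f)))
  readr::write_csv(tibble::tibble(known_ratio = tt$known_ratio,
                                  peaklist = files),
                   file.path(dir, "titration.csv"))
  fit <- quantify_titration(file.path(dir, "titration.csv"),
                            ion_mz(M_SER), ion_mz(M_THR))
  expect_equal(fit$slope, 0.8, tolerance = 1e-6)  # noise-free series
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  jpath <- file.path(dir, "fit.json")
  write_titration_report(fit, jpath, params = list(K = 4))
  parsed <- jsonlite::read_json(jpath)
  expect_equal(parsed$slope, 0.8, tolerance = 1e-6)
  expect_equal(length(parsed$points), 3)
})
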