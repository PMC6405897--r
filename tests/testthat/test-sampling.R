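test_that("overlay keeps exactly the individuals in habitat", {
  pat <- simulate_csr(100, seed = 1)
  full <- threshold_to_habitat(midpoint_displacement(0.5, 7, seed = 2), 1)
  empty <- threshold_to_habitat(midpoint_displacement(0.5, 7, seed = 2), 0)

  res_full <- overlay(pat, full)
  expect_equal(res_full$abundance, 100)
  expect_true(res_full$survived)
  res_empty <- overlay(pat, empty)
  expect_equal(res_empty$abundance, 0)
  expect_false(res_empty$survived)

  # hand-checked 2x2 map: habitat only in the lower-left quadrant
  m <- habitat_map(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  three <- point_pattern(c(0.1, 0.1, 0.9), c(0.1, 0.9, 0.9))
  res <- overlay(three, m)
  expect_equal(res$abundance, 1)
  expect_true(res$survived)
  expect_equal(npoints(three), 3)  # input unmodified

  # conservation: survivors + matrix points = total
  for (s in 1:5) {
    p <- simulate_thomas(thomas_params(80, 4, 0.03), seed = s)
    map <- threshold_to_habitat(midpoint_displacement(0.3, 7, seed = s), 0.25,
                                tie_seed = s)
    surv <- overlay(p, map)$abundance
    expect_equal(surv + sum(!is_habitat(map, p$x, p$y)), 80)
  }

  shifted <- point_pattern(0.5, 0.5, make_window(0, 0, 2, 2))
  expect_error(overlay(shifted, m), class = "fragsim_error_geometry")
})

test_that("estimate_survival matches small closed-form checks", {
  # CSR closed form at modest replication
  est <- estimate_survival(species_spec("csr", 10),
                           landscape_spec("fractal", 0.05, hurst = 0.5),
                           n_reps = 2000, master_seed = 1)
  expect_lt(abs(est$survival_prob - survival_csr(10, 0.05)),
            3 * sqrt(0.4013 * 0.5987 / 2000))

  # mean abundance = n * p; binomial cv
  est2 <- estimate_survival(species_spec("csr", 100),
                            landscape_spec("fractal", 0.2, hurst = 0.3),
                            n_reps = 1000, master_seed = 2)
  expect_lt(abs(est2$mean_abundance - 20), 3 * est2$se_mean_abundance)
  expect_lt(abs(est2$cv_abundance - sqrt(0.8 / 20)) / sqrt(0.8 / 20), 0.12)

  # determinism of the whole estimate under the master seed
  est3 <- estimate_survival(species_spec("csr", 100),
                            landscape_spec("fractal", 0.2, hurst = 0.3),
                            n_reps = 1000, master_seed = 2)
  expect_identical(est2$abundances, est3$abundances)

  expect_error(estimate_survival(species_spec("csr", 10),
                                 landscape_spec("fractal", 0.1, hurst = 0.5),
                                 n_reps = 1, master_seed = 1),
               class = "fragsim_error_parameter")
})

test_that("cv is reported missing (not zero) when nothing survives", {
  est <- estimate_survival(species_spec("csr", 5),
                           landscape_spec("fractal", 0, hurst = 0.5),
                           n_reps = 20, master_seed = 1)
  expect_equal(est$mean_abundance, 0)
  expect_true(is.na(est$cv_abundance))
  expect_equal(est$survival_prob, 0)
})

test_that("run_scenario_cell returns a complete flat row", {
  row <- run_scenario_cell(list(process = "thomas", n_P = 60, n_C = 3,
                                sigma = 0.05, habitat_amount = 0.2,
                                hurst = 0.5, n_reps = 50, master_seed = 7))
  expect_s3_class(row, "data.frame")
  expect_equal(nrow(row), 1)
  expect_equal(row$n_C, 3)
  expect_true(row$survival_prob >= 0 && row$survival_prob <= 1)

  degenerate <- run_scenario_cell(list(process = "csr", n_P = 10,
                                       habitat_amount = 0, hurst = 0.5,
                                       n_reps = 100, master_seed = 1))
  expect_equal(degenerate$survival_prob, 0)

  strauss_row <- run_scenario_cell(list(process = "strauss", n_P = 25,
                                        gamma = 0.5, habitat_amount = 0.2,
                                        hurst = 0.5, n_reps = 30,
                                        master_seed = 3, n_sweeps = 2000))
  expect_equal(strauss_row$r, 0.2)
})

test_that("wilson interval stays informative at the boundaries", {
  ci <- wilson_interval(1, 100)
  expect_lt(ci["lower"], 1)
  expect_equal(unname(ci["upper"]), 1)
  ci0 <- wilson_interval(0, 100)
  expect_gt(ci0["upper"], 0)
  mid <- wilson_interval(0.5, 1000)
  expect_lt(abs(mean(mid) - 0.5), 1e-6)
})
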