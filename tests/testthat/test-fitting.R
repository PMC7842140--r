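p_c3h <- reference_params("C3H/He")

test_that("r_squared matches its defining identities", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 3)), 0.5)  # SSres=1, SStot=2
  obs <- c(4, 7, 1, 9)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_error(r_squared(numeric(0), numeric(0)), "non-empty")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("onset OLS is exact on collinear data", {
  obs <- data.frame(dose = c(40, 60, 80),
                    onset_week = c(9.6390068, 4.5706930, 0.9746671))
  fit <- fit_onset_model(obs)
  expect_equal(fit$params$t1, 55.75, tolerance = 1e-6)
  expect_equal(fit$params$t2, -12.5, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-6)
  expect_equal(fit$n_points, 3L)
  expect_length(fit$residuals, 3L)
  expect_identical(fit$free, c("t1", "t2"))
  expect_true(is.na(fit$params$a))  # onset fit carries only t1, t2
})

test_that("symmetric perturbations reduce to the line through group means", {
  # +-1 week at two doses: OLS equals the two-point line through the means
  obs <- data.frame(dose = c(40, 40, 60, 60),
                    onset_week = c(9.6390068 + 1, 9.6390068 - 1,
                                   4.5706930 + 1, 4.5706930 - 1))
  fit <- fit_onset_model(obs)
  expect_equal(fit$params$t1, 55.75, tolerance = 1e-6)
  expect_equal(fit$params$t2, -12.5, tolerance = 1e-6)
})

test_that("onset fit rejects singular designs", {
  one_dose <- data.frame(dose = rep(60, 4), onset_week = c(4, 4, 4, 4))
  expect_error(fit_onset_model(one_dose), "singular")
  expect_error(fit_onset_model(data.frame(dose = c(40, 60),
                                          onset_week = c(9, 5))),
               "at least 3")
})

test_that("onset validation applies fixed parameters without refitting", {
  p <- dvr_params(t1 = 55.75, t2 = -12.5)
  exact <- exact_onsets(p, c(45, 65, 85))
  expect_equal(validate_onset_model(p, exact)$r_squared, 1)
  # constant predictions equal to the observation mean -> R^2 = 0
  flat <- dvr_params(t1 = 5 + 12.5 * log(40), t2 = -12.5)
  obs <- data.frame(dose = rep(40, 3), onset_week = c(4, 5, 6))
  expect_equal(validate_onset_model(flat, obs)$r_squared, 0)
  # hand-computed arithmetic oracle
  obs <- data.frame(dose = c(40, 60, 80), onset_week = c(9, 5, 1))
  expect_equal(validate_onset_model(p, obs)$r_squared, 0.98146012,
               tolerance = 1e-6)
  expect_error(validate_onset_model(p, obs[0, ]), "empty|at least|positive")
})

test_that("volume fit recovers generating parameters from noise-free data", {
  pts <- exact_volume_points(p_c3h)
  fit <- fit_volume_model(pts)
  expect_equal(fit$params$a, 0.0155, tolerance = 1e-4)
  expect_equal(fit$params$b, 0.40, tolerance = 1e-4)
  expect_equal(fit$params$D0, 30, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)
  expect_true(fit$converged)
  # self-consistency: reported R^2 equals r_squared on its own predictions
  expect_equal(fit$r_squared, r_squared(fit$observed, fit$fitted))
})

test_that("noise-free recovery holds across generating parameter sets", {
  cases <- list(
    dvr_params(a = 0.010, b = 0.6, D0 = 20),
    dvr_params(a = 0.030, b = 0.3, D0 = 35),
    dvr_params(a = 0.0155, b = 1.1, D0 = 10)
  )
  for (gen in cases) {
    pts <- exact_volume_points(gen, doses = c(45, 60, 75, 90))
    fit <- fit_volume_model(pts)
    expect_equal(fit$params$a, gen$a, tolerance = 1e-4)
    expect_equal(fit$params$b, gen$b, tolerance = 1e-4)
    expect_equal(fit$params$D0, gen$D0, tolerance = 1e-4)
  }
})

test_that("one-parameter transfer recovers a changed exponent exactly", {
  p_new <- dvr_params(a = 0.0155, b = 0.28, D0 = 30)
  pts <- exact_volume_points(p_new, doses = c(45, 65, 85))
  fit <- fit_volume_model(pts, free = "b",
                          fixed = dvr_params(a = 0.0155, D0 = 30))
  expect_equal(fit$params$b, 0.28, tolerance = 1e-6)
  expect_equal(fit$params$a, 0.0155)   # held fixed
  expect_equal(fit$params$D0, 30)      # held fixed
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("shifting all log-volumes perturbs the residual optimum detectably", {
  # guards against silent data-scale bugs: a constant multiplicative shift
  # of the volumes must change the fitted solution / residual structure
  pts <- exact_volume_points(p_c3h)
  base <- fit_volume_model(pts)
  shifted <- pts
  shifted$volume <- shifted$volume * 10^0.3
  refit <- fit_volume_model(shifted)
  expect_gt(sum(refit$residuals^2) + abs(refit$params$a - base$params$a) +
              abs(refit$params$D0 - base$params$D0), 1e-4)
})

test_that("volume fit validates its inputs and flags non-convergence paths", {
  pts <- exact_volume_points(p_c3h)
  bad <- pts; bad$volume[3] <- -1
  expect_error(fit_volume_model(bad), "positive volume")
  expect_error(fit_volume_model(pts, free = character(0)), "free")
  expect_error(fit_volume_model(pts, free = "b", fixed = dvr_params()),
               "fixed value required")
  expect_error(fit_volume_model(pts[1:2, ], free = c("a", "b", "D0")),
               "fewer points")
})

test_that("fitted R^2 never exceeds one", {
  set.seed(11)
  pts <- exact_volume_points(p_c3h)
  pts$volume <- pts$volume * 10^rnorm(nrow(pts), 0, 0.2)
  fit <- fit_volume_model(pts)
  expect_lte(fit$r_squared, 1)
  expect_lte(fit_onset_model(data.frame(dose = c(40, 60, 80, 40),
                                        onset_week = c(10, 4, 1, 8))
             )$r_squared, 1)
})
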