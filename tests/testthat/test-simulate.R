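p_c3h <- reference_params("C3H/He")
p_c57 <- reference_params("C57BL/6")

test_that("scan schedule follows the biweekly-then-late rule", {
  cfg <- sim_config()
  expect_equal(build_schedule(cfg, first_week = 1),
               c(-1, 1, 3, 5, 7, 9, 11, 13, 18, 23, 26))
  expect_equal(build_schedule(cfg, first_week = 2),
               c(-1, 2, 4, 6, 8, 10, 12, 14, 19, 24, 26))
  short <- sim_config(max_followup = 3, late_start = 2.5)
  expect_equal(build_schedule(short, first_week = 1), c(-1, 1, 3))
  set.seed(1)
  drawn <- replicate(50, build_schedule(cfg)[2])
  expect_true(all(drawn %in% c(1, 2)))
  expect_gt(length(unique(drawn)), 1)
})

test_that("sham controls never develop lesions and are censored", {
  cfg <- sim_config(seed = 3)
  set.seed(3)
  m <- simulate_mouse(0, p_c3h, cfg, "ctrl")
  expect_true(all(m$volumes == 0))
  expect_true(is.na(m$observed_onset))
  expect_identical(m$event, 0L)
  expect_equal(m$last_week, 26)
})

test_that("noise-free trajectories equal the growth law exactly", {
  cfg <- sim_config(sigma_log10 = 0)
  set.seed(5)
  m <- simulate_mouse(80, p_c3h, cfg, "hi")
  expect_equal(m$observed_onset, m$scan_weeks[m$scan_weeks >= 0.9746671][1])
  post <- m$scan_weeks >= m$observed_onset
  expect_equal(m$volumes[post],
               predict_volume(80, m$scan_weeks[post], p_c3h,
                              warn_pre_onset = FALSE))
  expect_true(all(m$volumes[!post] == 0))
  expect_true(all(m$volumes[m$scan_weeks < 0.9746671] == 0))
})

test_that("sacrifice triggers at the first scan crossing the threshold", {
  # threshold crossing time: (log10 60 / 0.775)^(1/0.4) = 7.9738 weeks
  cfg <- sim_config(sigma_log10 = 0, sacrifice_threshold = 60)
  for (fw in c(1, 2)) {
    set.seed(fw)
    m <- simulate_mouse(80, p_c3h, cfg, paste0("m", fw))
    sched <- build_schedule(cfg, first_week = m$scan_weeks[2])
    expected_week <- sched[sched >= 7.9738395][1]
    expect_identical(m$event, 1L)
    expect_equal(m$last_week, expected_week)
    expect_gte(m$volumes[length(m$volumes)], 60)  # terminal diagnostic scan
    expect_true(all(m$volumes[-length(m$volumes)] < 60))
  }
})

test_that("cohorts are deterministic and have the study layout", {
  cfg <- sim_config(seed = 9)
  coh1 <- simulate_cohort(cfg)
  coh2 <- simulate_cohort(cfg)
  expect_equal(length(coh1$mice), 20L)  # 2 strains x (3 doses x 3 + 1 sham)
  expect_identical(cohort_table(coh1), cohort_table(coh2))
  expect_identical(survival_table(coh1), survival_table(coh2))
  tab <- cohort_table(coh1)
  expect_setequal(unique(tab$dose_gy[tab$strain == "C3H/He"]),
                  c(0, 40, 60, 80))
  expect_setequal(unique(tab$dose_gy[tab$strain == "C57BL/6"]),
                  c(0, 45, 65, 85))
})

test_that("existing animals are unchanged when the cohort grows", {
  cfg <- sim_config(seed = 9)
  bigger <- sim_config(seed = 9, strains = list(
    strain_spec("C3H/He", p_c3h, c(40, 60, 80), n_per_dose = 5),
    strain_spec("C57BL/6", p_c57, c(45, 65, 85))))
  small <- simulate_cohort(cfg)
  big <- simulate_cohort(bigger)
  for (id in names(small$mice))
    expect_identical(small$mice[[id]], big$mice[[id]])
})

test_that("noise-free extreme dose groups meet their analytic fates", {
  coh <- simulate_cohort(sim_config(sigma_log10 = 0, seed = 4))
  surv <- survival_table(coh)
  lo <- surv[surv$dose_gy %in% c(40, 45), ]
  hi <- surv[surv$dose_gy %in% c(80, 85), ]
  expect_true(all(lo$event == 0) && all(lo$last_week == 26))
  expect_true(all(hi$event == 1) && all(hi$last_week < 26))
})

test_that("mean observed onset is dose-ordered within each strain", {
  for (seed in 1:5) {
    tab <- cohort_table(simulate_cohort(sim_config(seed = seed)))
    for (s in unique(tab$strain)) {
      ons <- onset_observations(tab[tab$strain == s, ])
      m <- tapply(ons$onset_week, ons$dose, mean)
      expect_true(all(diff(m[order(as.numeric(names(m)))]) <= 0))
    }
  }
})

test_that("the slower-exponent strain reaches sacrifice later at top dose", {
  surv <- survival_table(simulate_cohort(sim_config(sigma_log10 = 0,
                                                    seed = 2)))
  t_c3h <- surv$last_week[surv$strain == "C3H/He" & surv$dose_gy == 80]
  t_c57 <- surv$last_week[surv$strain == "C57BL/6" & surv$dose_gy == 85]
  expect_lt(max(t_c3h), min(t_c57))
})

test_that("volumes are clipped at the brain-volume cap with a warning", {
  cfg <- sim_config(sigma_log10 = 0, sacrifice_threshold = 400,
                    brain_volume_cap = 200, detection_threshold = 1)
  set.seed(8)
  expect_warning(m <- simulate_mouse(80, p_c3h, cfg, "cap"), "cap")
  expect_true(all(m$volumes <= 200))
})

test_that("volume_points applies the post-onset positive-volume rule", {
  coh <- simulate_cohort(sim_config(sigma_log10 = 0, seed = 6))
  tab <- cohort_table(coh)
  pts <- volume_points(tab)
  expect_true(all(pts$volume > 0))
  expect_false(any(pts$dose == 0))   # controls contribute no points
  ons <- onset_observations(tab)
  for (i in seq_len(nrow(ons))) {
    sel <- pts[pts$mouse_id == ons$mouse_id[i], ]
    expect_true(all(sel$t >= ons$onset_week[i]))
  }
  # row count equals the per-mouse post-onset scan counts
  n_expected <- sum(vapply(coh$mice, function(m) {
    if (is.na(m$observed_onset)) return(0L)
    sum(m$scan_weeks >= m$observed_onset & m$volumes > 0)
  }, integer(1)))
  expect_equal(nrow(pts), n_expected)
})
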