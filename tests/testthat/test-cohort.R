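test_that("generation is reproducible from the seed and schema-stable", {
  cfg <- generator_config(seed = 5)
  t1 <- generate_cohort(cfg)
  t2 <- generate_cohort(cfg)
  expect_identical(t1, t2)
  t3 <- generate_cohort(generator_config(seed = 6))
  expect_identical(names(t3), names(t1))
  expect_identical(dim(t3), dim(t1))
  expect_false(identical(t1$nrt_threshold_cl, t3$nrt_threshold_cl))
})

test_that("cohort tables satisfy their structural invariants", {
  tab <- generate_cohort(generator_config(n_subjects = 40, seed = 17))
  expect_true(all(tab$nrt_threshold_cl >= 0 & tab$nrt_threshold_cl <= 255))
  expect_true(all(tab$impedance_kohm >= 2.86 & tab$impedance_kohm <= 19.07))
  expect_true(all(tab$x_oc_frac >= 0 & tab$x_oc_frac <= 1))
  expect_true(all(tab$cnf_hz > 0))
  by_sub <- split(tab, tab$subject_id)
  for (s in by_sub) {
    expect_length(unique(s$array_type), 1L)
    expect_length(unique(s$scalar), 1L)
    # characteristic frequency rises from the apical to the basal contact
    expect_true(all(diff(s$cnf_hz[order(s$electrode)]) > 0))
  }
  # ages are internally consistent
  expect_true(all(tab$age_implant_yr >= tab$age_deaf_yr))
  expect_true(all(tab$age_test_yr > tab$age_implant_yr))
  # straight and slim-straight arrays never translocate
  sub <- tab[!duplicated(tab$subject_id), ]
  expect_true(all(sub$scalar[sub$array_type != "PMA"] == "ST"))
})

test_that("noiseless null configuration collapses to the intercept", {
  cfg <- generator_config(
    n_subjects = 5, seed = 2, sigma_b = 0, sigma_e = 0,
    spline_shape = rep(0, 5),
    fixed_effects = list(intercept_cl = 150, beta_imp_sq = 0,
                         beta_dist_sq = 0, beta_st = 0,
                         array = c(SSA = 0, PMA = 0, SA = 0),
                         etiology = c(ProgressiveSNHL = 0, Viral = 0,
                                      Genetic = 0, Autoimmune = 0,
                                      Ototoxic = 0, Otosclerosis = 0),
                         beta_age_test = 0, beta_duration = 0))
  tab <- generate_cohort(cfg)
  expect_true(all(tab$nrt_threshold_cl == 150))
})

test_that("cohort summaries match hand-computed repeated-measure values", {
  flat <- make_mini_cohort(list(A = c(1, 1), B = c(1, 1)))
  s <- summarize_cohort(flat)
  expect_equal(s$nrt$within_sd, 0)
  expect_equal(s$nrt$between_sd, 0)
  # one-way ANOVA by hand: within sqrt(2), between 2*sqrt(2)
  two <- make_mini_cohort(list(A = c(0, 2), B = c(4, 6)))
  s2 <- summarize_cohort(two)
  expect_equal(s2$nrt$mean, 3)
  expect_equal(s2$nrt$within_sd, sqrt(2), tolerance = 1e-12)
  expect_equal(s2$nrt$between_sd, 2 * sqrt(2), tolerance = 1e-12)
  expect_warning(summarize_cohort(make_mini_cohort(list(A = c(1, 2)))),
                 "single subject")
})

test_that("large-cohort summaries converge to the calibration targets", {
  tab <- generate_cohort(generator_config(n_subjects = 400, seed = 23))
  s <- summarize_cohort(tab)
  expect_equal(s$nrt$mean, 169.68, tolerance = 2 / 169.68)
  expect_equal(s$nrt$within_sd, 13.66, tolerance = 1 / 13.66)
  expect_equal(s$nrt$between_sd, 18.60, tolerance = 2 / 18.60)
  expect_equal(s$impedance$mean, 8.71, tolerance = 0.3 / 8.71)
  expect_equal(s$insertion$mean, 343, tolerance = 4 / 343)
})

test_that("PMA translocation fraction converges to its probability", {
  cfg <- generator_config(n_subjects = 800, n_electrodes = 2, seed = 31,
                          array_probs = c(SSA = 0, PMA = 1, SA = 0))
  s <- summarize_cohort(generate_cohort(cfg))
  expect_equal(s$pma_sv_fraction, 0.3548, tolerance = 0.06 / 0.3548)
})

test_that("the double-bump profile has its documented features", {
  co <- default_double_bump_shape()
  grid <- seq(300, 16000, by = 50)
  v <- eval_tp_spline(grid, co)
  # steep rise from 500 to 3000 Hz
  expect_gt(eval_tp_spline(3000, co), eval_tp_spline(500, co) + 5)
  # dip in the 4000-5000 Hz region relative to the 3000 Hz shoulder
  expect_lt(eval_tp_spline(5000, co), eval_tp_spline(3000, co))
  # 10000 Hz is the global maximum over the audible grid
  expect_equal(grid[which.max(v)], 10000)
  i10 <- which(grid == 10000)
  expect_true(all(v[i10] >= v[c(i10 - 1, i10 + 1)]))
  # ascending base-to-apex trend overall
  expect_gt(eval_tp_spline(12000, co), eval_tp_spline(500, co))
  expect_equal(eval_tp_spline(grid, rep(0, 5)), rep(0, length(grid)))
})

test_that("generator configuration is validated and round-trips as YAML", {
  expect_error(generator_config(array_probs = c(SSA = 0.5, PMA = 0.2,
                                                SA = 0.2)),
               "sum to 1")
  expect_error(generator_config(p_sv_translocation_pma = 1.5), "\\[0, 1\\]")
  expect_error(generator_config(nonsense = 1), "unknown")
  expect_error(generator_config(spline_shape = c(1, 2)), "knot count")
  cfg <- generator_config(n_subjects = 12, seed = 44)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, f)
  cfg2 <- read_generator_config(f)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-9)
  expect_identical(generate_cohort(cfg2), generate_cohort(cfg))
})

test_that("calibration back-solves the residual structure", {
  # with deliberately wrong starting values the calibrated configuration
  # reproduces the targets on an independent cohort
  start <- generator_config(sigma_b = 5, sigma_e = 5)
  start$fixed_effects$intercept_cl <- 140
  cal <- calibrate_generator(start, n_subjects = 600, seed = 81,
                             refine = 1)
  chk <- cal
  chk$n_subjects <- 600L
  chk$seed <- 82L
  s <- summarize_cohort(generate_cohort(chk))
  expect_equal(s$nrt$mean, 169.68, tolerance = 2.5 / 169.68)
  expect_equal(s$nrt$within_sd, 13.66, tolerance = 1.2 / 13.66)
  expect_equal(s$nrt$between_sd, 18.60, tolerance = 2.5 / 18.60)
})
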