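# Fixtures built in code at test time.

# grouped regression data with known structure
make_grouped_data <- function(n_groups = 3, n_per = 4, seed = 101,
                              sigma_b = 1.5, sigma_e = 0.8,
                              beta = c(2, 1.2)) {
  set.seed(seed)
  n <- n_groups * n_per
  d <- data.frame(g = rep(seq_len(n_groups), each = n_per),
                  x = stats::rnorm(n))
  d$y <- beta[1] + beta[2] * d$x +
    rep(stats::rnorm(n_groups, 0, sigma_b), each = n_per) +
    stats::rnorm(n, 0, sigma_e)
  d
}

# minimal cohort table wrapping explicit per-subject NRT values, with the
# covariate columns summarize_cohort() expects
make_mini_cohort <- function(values_by_subject) {
  rows <- lapply(names(values_by_subject), function(s) {
    v <- values_by_subject[[s]]
    data.frame(subject_id = s, electrode = seq_along(v),
               array_type = "PMA", scalar = "ST",
               insertion_angle_deg = 346, impedance_kohm = 8.71,
               nrt_threshold_cl = v)
  })
  do.call(rbind, rows)
}

# geometry toy table: one subject, explicit spacings
make_geometry_toy <- function(A = 8, theta = 360, Y = c(0, 5)) {
  data.frame(subject_id = "S1", electrode = seq_along(Y),
             array_type = "PMA", diameter_A_mm = A,
             insertion_angle_deg = theta, spacing_Y_mm = Y)
}
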