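# Synthetic implanted-subject cohorts with the covariate structure of the
# study population (31 subjects x 22 electrodes, Nucleus devices) and the
# multivariate effect structure used as simulation ground truth, so that
# every downstream stage is testable by parameter recovery.

#' Default "double bump" frequency profile
#'
#' Ground-truth coefficients, on the [tp_spline()] basis with knots at 5000
#' and 10000 Hz, of the mean NRT-threshold-vs-frequency curve: a steep rise
#' from 500 to 3000 Hz, a dip in the 4000-5000 Hz region, and a dome with
#' its peak at 10000 Hz, over an ascending base-to-apex trend.
#'
#' The coefficients are derived in closed form on the kHz scale: the cubic
#' below the first knot is chosen with stationary points at 3 kHz (local
#' maximum) and 5 kHz (local minimum), the first truncated term cancels the
#' slope at 10 kHz (making it the dome peak), and the second truncated term
#' tempers the decline above 10 kHz. The overall amplitude is set so the
#' 500 Hz to 3000 Hz rise is about 12 C.L., a realistic magnitude for the
#' evoked-potential threshold swing across the array.
#'
#' @return Named numeric vector of length 5 (`f`, `f2`, `f3`, `k5000`,
#'   `k10000`), Hz-scale coefficients in C.L. per Hz^power.
#' @examples
#' f <- seq(500, 16000, by = 100)
#' curve <- eval_tp_spline(f, default_double_bump_shape())
#' @export
default_double_bump_shape <- function() {
  b3 <- 0.35 # amplitude, C.L. per kHz^3
  khz <- c(45 * b3, -12 * b3, b3, -1.4 * b3, 0.6856 * b3)
  out <- khz / c(1e3, 1e6, 1e9, 1e9, 1e9)
  names(out) <- c("f", "f2", "f3", "k5000", "k10000")
  out
}

#' Synthetic cohort generator configuration
#'
#' Ground-truth coefficients, variance components and sampling
#' distributions for [generate_cohort()]. Defaults reproduce the study
#' population: 31 subjects with 22 active electrodes each, array mix
#' 27 PMA / 2 SA / 2 SSA, impedances 8.71 kOhm (between-subject SD 2.05,
#' within 1.60, clipped to the observed 2.86-19.07 kOhm range), cochlear
#' duct lengths 35.05 +/- 4.68 mm (clipped to 26.38-43.42), per-array
#' insertion angles PMA 346 +/- 22, SA 312 +/- 46, SSA 335 +/- 35 degrees,
#' whole-array scala-vestibuli translocation of perimodiolar arrays with
#' probability 0.3548, and etiology frequencies 11/8/4/4/3/1 of 31. Fixed
#' effects default to the multivariate adjusted estimates (impedance^2
#' -0.11 C.L./kOhm^2, scala tympani -8.50 C.L., distance^2 +2.20
#' C.L./mm^2, ototoxic -24.33 C.L., age at test +0.29 C.L./yr, ...).
#'
#' `sigma_b` (between-subject SD of the random intercept), `sigma_e`
#' (residual SD) and `intercept_cl` are calibrated constants: they were
#' back-solved with [calibrate_generator()] so that a large generated
#' cohort reproduces the observed NRT grand mean (169.68 C.L.),
#' within-subject SD (13.66) and between-subject SD (18.60), part of which
#' is already explained by the covariates and the frequency profile.
#'
#' @param n_subjects,n_electrodes Cohort dimensions.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @param ... Named overrides of any default component (e.g.
#'   `sigma_e = 0`, `fixed_effects = ...`).
#' @return List of class `"generator_config"`.
#' @export
generator_config <- function(n_subjects = 31, n_electrodes = 22, seed = 1,
                             ...) {
  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_electrodes = as.integer(n_electrodes),
    seed = as.integer(seed),
    fixed_effects = list(
      intercept_cl = 161.6438,
      beta_imp_sq = -0.11,
      beta_dist_sq = 2.20,
      beta_st = -8.50,
      array = c(SSA = 0, PMA = -5.94, SA = 13.43),
      etiology = c(ProgressiveSNHL = 0, Viral = 2.55, Genetic = -3.44,
                   Autoimmune = -10.50, Ototoxic = -24.33,
                   Otosclerosis = -4.09),
      beta_age_test = 0.29,
      beta_duration = -0.17
    ),
    spline_shape = default_double_bump_shape(),
    knots = c(5000, 10000),
    sigma_b = 13.2806,
    sigma_e = 12.9902,
    impedance_model = list(mean = 8.71, sd_between = 2.05,
                           sd_within = 1.60, clip = c(2.86, 19.07)),
    insertion_model = list(PMA = c(mean = 346, sd = 22),
                           SA = c(mean = 312, sd = 46),
                           SSA = c(mean = 335, sd = 35)),
    cdl_model = list(mean = 35.05, sd = 4.68, clip = c(26.38, 43.42)),
    distance_model = list(mean = 0.6, sd_between = 0.25, sd_within = 0.2,
                          clip = c(0.05, 2.5)),
    p_sv_translocation_pma = 0.3548,
    array_probs = c(SSA = 2, PMA = 27, SA = 2) / 31,
    etiology_probs = c(ProgressiveSNHL = 11, Genetic = 8, Autoimmune = 4,
                       Ototoxic = 4, Otosclerosis = 3, Viral = 1) / 31,
    age_model = list(deaf_mean = 40.26, deaf_sd = 23.20,
                     deaf_clip = c(0, 80), dur_mean = 5.30, dur_sd = 5.32,
                     dur_clip = c(1, 30), wait_range = c(0.5, 6)),
    total_angle = 990,
    round_clip = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown generator_config field(s): ",
         paste(unknown, collapse = ", "))
  }
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$n_subjects < 1 || cfg$n_electrodes < 1) {
    stop("cohort dimensions must be positive")
  }
  if (cfg$sigma_b < 0 || cfg$sigma_e < 0) {
    stop("variance components must be non-negative SDs")
  }
  if (abs(sum(cfg$array_probs) - 1) > 1e-8) {
    stop("array_probs must sum to 1 (array mix inconsistent with cohort ",
         "size)")
  }
  if (abs(sum(cfg$etiology_probs) - 1) > 1e-8) {
    stop("etiology_probs must sum to 1")
  }
  p <- cfg$p_sv_translocation_pma
  if (p < 0 || p > 1) stop("translocation probability must lie in [0, 1]")
  if (length(cfg$spline_shape) != 3 + length(cfg$knots)) {
    stop("spline_shape length must match the knot count")
  }
  invisible(cfg)
}

#' Read or write a generator configuration as YAML
#'
#' @param file Path to a YAML file.
#' @param config A [generator_config()] object.
#' @return `read_generator_config()` returns a `generator_config`;
#'   `write_generator_config()` returns `file` invisibly.
#' @export
read_generator_config <- function(file) {
  raw <- yaml::read_yaml(file)
  raw$fixed_effects$array <- unlist(raw$fixed_effects$array)
  raw$fixed_effects$etiology <- unlist(raw$fixed_effects$etiology)
  raw$spline_shape <- unlist(raw$spline_shape)
  raw$array_probs <- unlist(raw$array_probs)
  raw$etiology_probs <- unlist(raw$etiology_probs)
  for (nm in c("impedance_model", "insertion_model", "cdl_model",
               "distance_model", "age_model")) {
    raw[[nm]] <- lapply(raw[[nm]], unlist)
  }
  do.call(generator_config, c(raw[c("n_subjects", "n_electrodes", "seed")],
                              raw[setdiff(names(raw),
                                          c("n_subjects", "n_electrodes",
                                            "seed"))]))
}

#' @rdname read_generator_config
#' @export
write_generator_config <- function(config, file) {
  stopifnot(inherits(config, "generator_config"))
  # named atomic vectors must become YAML maps to keep their names
  listify <- function(x) {
    if (is.list(x)) {
      lapply(x, listify)
    } else if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else {
      x
    }
  }
  yaml::write_yaml(listify(unclass(config)), file, precision = 15)
  invisible(file)
}

rnorm_clip <- function(n, mean, sd, clip) {
  pmin(pmax(stats::rnorm(n, mean, sd), clip[1]), clip[2])
}

#' Generate a synthetic implanted-subject cohort
#'
#' Draws per-subject geometry (cochlear duct length, hence diameter A;
#' insertion angle by array type), array type, whole-array
#' scala-vestibuli translocation (perimodiolar arrays only), correlated
#' ages (age at implantation = age of profound deafness + its duration;
#' age at test later still), impedances and electrode-modiolus distances
#' (subject-level shift plus electrode-level noise), maps every electrode
#' to its characteristic neuron frequency through the geometry chain, and
#' assembles NRT thresholds as
#' \deqn{NRT_{ij} = \mu + s(CNF_{ij}) + \beta_{imp} imp_{ij}^2 +
#'   \beta_{dist} dist_{ij}^2 + \beta_{ST} 1[ST_i] + array_i + etiology_i +
#'   \beta_{age} age_i + \beta_{dur} dur_i + b_i + \epsilon_{ij}}
#' with \eqn{b_i \sim N(0, \sigma_b^2)}, \eqn{\epsilon_{ij} \sim
#' N(0, \sigma_e^2)}, finally rounded to integer current levels and
#' clipped to the device range \[0, 255\] (unless `round_clip = FALSE`).
#'
#' When a drawn (duct length, insertion angle) pair is too small to contain
#' the full array, the angle is raised to the minimum geometrically
#' consistent value (full insertions only, as in the study population).
#'
#' @param config A [generator_config()]; generation is a pure function of
#'   it (the seed included).
#' @param arrays Array geometry registry, see [array_registry()].
#' @return Data frame (a cohort table) with one row per
#'   (subject, electrode): identifiers, covariates, `x_oc_frac`,
#'   `z_sg_frac`, `cnf_hz` and `nrt_threshold_cl`.
#' @export
generate_cohort <- function(config = generator_config(),
                            arrays = array_registry()) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  set.seed(config$seed)
  ns <- config$n_subjects
  ne <- config$n_electrodes
  fe <- config$fixed_effects

  atype <- sample(names(config$array_probs), ns, replace = TRUE,
                  prob = config$array_probs)
  cdl <- rnorm_clip(ns, config$cdl_model$mean, config$cdl_model$sd,
                    config$cdl_model$clip)
  diameter_A <- cdl / cdl_from_diameter(1, config$total_angle)
  theta <- vapply(seq_len(ns), function(i) {
    m <- config$insertion_model[[atype[i]]]
    stats::rnorm(1, m[["mean"]], m[["sd"]])
  }, numeric(1))
  # full insertion: the arc of electrode 1 must contain the array span
  span <- vapply(atype, function(a) max(arrays[[a]]$spacings_mm),
                 numeric(1))
  theta_min <- 235 * expm1((span + 0.1) / (2.62 * diameter_A))
  theta <- pmin(pmax(theta, theta_min), config$total_angle)

  sv <- atype == "PMA" &
    stats::runif(ns) < config$p_sv_translocation_pma
  scalar <- ifelse(sv, "SV", "ST")
  etio <- sample(names(config$etiology_probs), ns, replace = TRUE,
                 prob = config$etiology_probs)
  am <- config$age_model
  age_deaf <- rnorm_clip(ns, am$deaf_mean, am$deaf_sd, am$deaf_clip)
  dur_deaf <- rnorm_clip(ns, am$dur_mean, am$dur_sd, am$dur_clip)
  age_implant <- age_deaf + dur_deaf
  age_test <- age_implant + stats::runif(ns, am$wait_range[1],
                                         am$wait_range[2])
  imp_subject <- stats::rnorm(ns, 0, config$impedance_model$sd_between)
  dist_subject <- stats::rnorm(ns, config$distance_model$mean,
                               config$distance_model$sd_between)
  b_i <- stats::rnorm(ns, 0, config$sigma_b)

  sid <- sprintf("S%03d", seq_len(ns))
  tab <- data.frame(
    subject_id = rep(sid, each = ne),
    electrode = rep(seq_len(ne), times = ns),
    array_type = factor(rep(atype, each = ne),
                        levels = c("SSA", "PMA", "SA")),
    diameter_A_mm = rep(diameter_A, each = ne),
    insertion_angle_deg = rep(theta, each = ne),
    scalar = factor(rep(scalar, each = ne), levels = c("SV", "ST")),
    etiology = factor(rep(etio, each = ne),
                      levels = names(config$etiology_probs)),
    age_deaf_yr = rep(age_deaf, each = ne),
    duration_deaf_yr = rep(dur_deaf, each = ne),
    age_implant_yr = rep(age_implant, each = ne),
    age_test_yr = rep(age_test, each = ne),
    stringsAsFactors = FALSE
  )
  n <- nrow(tab)
  tab$impedance_kohm <- pmin(pmax(
    config$impedance_model$mean + rep(imp_subject, each = ne) +
      stats::rnorm(n, 0, config$impedance_model$sd_within),
    config$impedance_model$clip[1]), config$impedance_model$clip[2])
  tab$distance_mm <- pmin(pmax(
    rep(dist_subject, each = ne) +
      stats::rnorm(n, 0, config$distance_model$sd_within),
    config$distance_model$clip[1]), config$distance_model$clip[2])

  tab <- map_cohort_cnf(tab, sg_map = "identity", arrays = arrays,
                        total_angle = config$total_angle)

  eta <- fe$intercept_cl +
    eval_tp_spline(tab$cnf_hz, config$spline_shape, config$knots) +
    fe$beta_imp_sq * tab$impedance_kohm^2 +
    fe$beta_dist_sq * tab$distance_mm^2 +
    fe$beta_st * (tab$scalar == "ST") +
    fe$array[as.character(tab$array_type)] +
    fe$etiology[as.character(tab$etiology)] +
    fe$beta_age_test * tab$age_test_yr +
    fe$beta_duration * tab$duration_deaf_yr +
    rep(b_i, each = ne) +
    stats::rnorm(n, 0, config$sigma_e)
  tab$nrt_threshold_cl <- if (isTRUE(config$round_clip)) {
    pmin(pmax(round(eta), 0), 255)
  } else {
    eta
  }
  rownames(tab) <- NULL
  tab
}

within_subject_sd <- function(y, g) {
  g <- factor(g)
  ni <- as.integer(table(g))
  if (sum(ni - 1) == 0) return(NA_real_)
  dev <- y - stats::ave(y, g)
  sqrt(sum(dev^2) / sum(ni - 1))
}

#' Summary statistics of a cohort table
#'
#' Reproduces the repeated-measurement summaries used to describe the
#' study population: for NRT threshold and impedance, the grand mean
#' (mean of per-subject means), the pooled within-subject SD
#' \deqn{\sqrt{\sum_i \sum_j (y_{ij} - \bar y_i)^2 / \sum_i (n_i - 1)}}
#' (the Bland-Altman one-way ANOVA estimator), the between-subject SD
#' (SD of per-subject means) and the range; plus per-array and overall
#' insertion-angle means and the scala-vestibuli fraction among
#' perimodiolar-array subjects.
#'
#' @param table A cohort table as produced by [generate_cohort()] (or read
#'   with [read_cohort()]).
#' @return List with components `nrt`, `impedance` (each: `mean`,
#'   `within_sd`, `between_sd`, `min`, `max`), `insertion` (overall and
#'   per-array means over subjects), `pma_sv_fraction`, `n_subjects`,
#'   `n_obs`. With a single subject the between-subject SDs are `NA` and
#'   a warning is raised.
#' @export
summarize_cohort <- function(table) {
  need <- c("subject_id", "nrt_threshold_cl", "impedance_kohm",
            "insertion_angle_deg", "array_type", "scalar")
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "))
  }
  g <- factor(table$subject_id)
  if (nlevels(g) < 2) {
    warning("single subject: between-subject SD is undefined")
  }
  one <- function(y) {
    m <- tapply(y, g, mean)
    list(mean = mean(m), within_sd = within_subject_sd(y, g),
         between_sd = if (nlevels(g) >= 2) stats::sd(m) else NA_real_,
         min = min(y), max = max(y))
  }
  sub <- table[!duplicated(table$subject_id), ]
  list(
    nrt = one(table$nrt_threshold_cl),
    impedance = one(table$impedance_kohm),
    insertion = list(
      mean = mean(sub$insertion_angle_deg),
      by_array = tapply(sub$insertion_angle_deg, sub$array_type, mean)
    ),
    pma_sv_fraction = if (any(sub$array_type == "PMA")) {
      mean(sub$scalar[sub$array_type == "PMA"] == "SV")
    } else {
      NA_real_
    },
    n_subjects = nlevels(g),
    n_obs = nrow(table)
  )
}

#' Calibrate the generator's residual structure to target summaries
#'
#' The covariates and the frequency profile explain part of the NRT
#' spread, so the free components (`sigma_e`, `sigma_b`, `intercept_cl`)
#' are back-solved rather than set directly. A large noise-free cohort
#' (`sigma_b = sigma_e = 0`, no rounding) measures the covariate-explained
#' within- and between-subject SDs (w0, b0) and the mean m0; then
#' \deqn{\sigma_e^2 = W^2 - w_0^2, \qquad
#'       \sigma_b^2 = B^2 - b_0^2 - \sigma_e^2 / n_e,}
#' (the second term because the between-subject SD is taken on subject
#' means, which retain 1/n_e of the residual variance), and the intercept
#' shifts by the mean gap. A few refinement iterations on full-noise
#' cohorts then absorb the small nonlinear effects (integer rounding and
#' clipping to the 0-255 device range).
#'
#' @param config Starting [generator_config()].
#' @param targets Target grand mean, within-subject SD and between-subject
#'   SD of NRT (defaults: the observed 169.68 / 13.66 / 18.60 C.L.).
#' @param n_subjects Size of the calibration cohort.
#' @param seed Seed for the calibration cohort.
#' @param refine Number of refinement iterations on full-noise cohorts.
#' @return A new `generator_config` with calibrated `sigma_e`, `sigma_b`
#'   and `intercept_cl`.
#' @export
calibrate_generator <- function(config = generator_config(),
                                targets = list(mean = 169.68,
                                               within_sd = 13.66,
                                               between_sd = 18.60),
                                n_subjects = 4000, seed = 20150705,
                                refine = 2) {
  cfg0 <- config
  cfg0$n_subjects <- as.integer(n_subjects)
  cfg0$seed <- as.integer(seed)
  cfg0$sigma_b <- 0
  cfg0$sigma_e <- 0
  cfg0$round_clip <- FALSE
  s0 <- summarize_cohort(generate_cohort(cfg0))
  w0 <- s0$nrt$within_sd
  b0 <- s0$nrt$between_sd
  m0 <- s0$nrt$mean
  if (w0 >= targets$within_sd) {
    stop(sprintf(paste0("covariates alone produce within-subject SD %.2f ",
                        ">= target %.2f; no residual SD can match"),
                 w0, targets$within_sd))
  }
  sigma2_e <- targets$within_sd^2 - w0^2
  sigma2_b <- targets$between_sd^2 - b0^2 - sigma2_e / config$n_electrodes
  if (sigma2_b < 0) {
    stop(sprintf(paste0("subject-level covariates alone produce ",
                        "between-subject SD %.2f >= target %.2f"),
                 b0, targets$between_sd))
  }
  out <- config
  out$sigma_e <- sqrt(sigma2_e)
  out$sigma_b <- sqrt(sigma2_b)
  out$fixed_effects$intercept_cl <-
    config$fixed_effects$intercept_cl + (targets$mean - m0)

  for (it in seq_len(refine)) {
    chk <- out
    chk$n_subjects <- as.integer(n_subjects)
    chk$seed <- as.integer(seed + it)
    s1 <- summarize_cohort(generate_cohort(chk))$nrt
    sigma2_e <- max(out$sigma_e^2 + targets$within_sd^2 - s1$within_sd^2, 0)
    sigma2_b <- max(out$sigma_b^2 + targets$between_sd^2 - s1$between_sd^2,
                    0)
    out$sigma_e <- sqrt(sigma2_e)
    out$sigma_b <- sqrt(sigma2_b)
    out$fixed_effects$intercept_cl <-
      out$fixed_effects$intercept_cl + (targets$mean - s1$mean)
  }
  out
}
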