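## Synthetic preclinical cohort generator.
##
## Emulates a multi-electrode direct-current study on a fast-growing murine
## mammary carcinoma: 8 groups x 2 genders x 10 animals, twice-weekly caliper
## measurements converted by V = pi*a*b^2/6, tumor latency of roughly 12-15
## days, treatment at ~0.5 cm^3 on day 31 post-inoculation, follow-up to day
## 49, multiplicative measurement noise, death hazards before and after
## treatment, and ethics-driven censoring of tumors reaching 2 cm^3.

#' Default experimental group table
#'
#' Eight groups: two controls (electrodes inserted, no current) and six
#' treated groups covering DC intensities of 2, 6 and 10 mA, exposure times
#' of 10 and 20 min, and three electrode-array geometries (collinear `C-I`,
#' paired `C-II`/`C-III`). Geometry and exposure time are metadata tags
#' here: they influence the model only through the per-group polarization
#' current and decay rate in [default_hyperparams()].
#'
#' @return A data.frame with columns `group`, `geometry`, `i` (mA),
#'   `t_exp` (min), `control`, `n_per_gender`.
#' @export
default_group_table <- function() {
  data.frame(
    group    = c("CG1", "CG2", "TG1", "TG2", "TG3", "TG4", "TG5", "TG6"),
    geometry = c("C-I", "C-II", "C-I", "C-II", "C-III", "C-II", "C-II", "C-II"),
    i        = c(0, 0, 2, 6, 2, 2, 6, 10),
    t_exp    = c(0, 0, 10, 20, 10, 10, 10, 10),
    control  = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    n_per_gender = 10L,
    stringsAsFactors = FALSE
  )
}

## Population-level parameter means per group and gender. Growth rates and
## treatment parameters are set to the scale reported for this tumor line:
## females grow faster (alpha ~ 0.49/d) than males (~ 0.42/d); polarization
## currents sit between ~1.4 and ~7.1 mA so that fitted i/i0 ratios land in
## the 1.0-1.5 band; gamma spans ~4-50/d. Latency statistics are
## gender- and group-specific.
group_param_means <- function() {
  g <- c("CG1", "CG2", "TG1", "TG2", "TG3", "TG4", "TG5", "TG6")
  rbind(
    data.frame(
      group = g, gender = "F",
      alpha = c(0.462, 0.490, 0.462, 0.490, 0.490, 0.490, 0.490, 0.490),
      beta  = c(0.024, 0.013, 0.009, 0.055, 0.026, 0.023, 0.001, 0.016),
      i0    = c(NA, NA, 1.561, 4.061, 1.413, 1.569, 4.415, 6.942),
      gamma = c(NA, NA, 17.742, 12.890, 26.291, 36.567, 49.672, 13.672),
      latency_mean = c(15.4, 13.2, 12.0, 11.6, 13.2, 12.6, 14.0, 15.0),
      latency_sd   = c(3.3, 2.2, 2.1, 3.6, 3.2, 4.1, 3.8, 4.8),
      stringsAsFactors = FALSE
    ),
    data.frame(
      group = g, gender = "M",
      alpha = c(0.426, 0.422, 0.426, 0.422, 0.422, 0.422, 0.422, 0.422),
      beta  = c(0.034, 0.049, 0.059, 0.078, 0.017, 0.058, 0.028, 0.014),
      i0    = c(NA, NA, 1.842, 4.147, 1.495, 1.516, 4.333, 7.119),
      gamma = c(NA, NA, 13.197, 4.536, 7.526, 12.742, 27.890, 10.291),
      latency_mean = c(11.8, 12.3, 11.0, 12.0, 11.5, 12.8, 12.2, 11.0),
      latency_sd   = c(4.2, 3.0, 2.0, 1.1, 2.0, 4.5, 3.9, 4.4),
      stringsAsFactors = FALSE
    )
  )
}

#' Default population hyperparameters for cohort simulation
#'
#' Gender- and group-specific population means for the growth and treatment
#' parameters, between-animal coefficients of variation, the measurement
#' noise level, death hazards, and the censoring rule.
#'
#' Mortality is calibrated analytically to the attrition pattern the
#' simulator emulates: a constant pre-treatment hazard such that 24.4% of
#' animals die in the 31 days before treatment, and a post-treatment death
#' probability of 13.48% among treatment-day survivors with early-weighted
#' timing (84.21% of those deaths within 72 h of treatment, the remainder
#' spread over the rest of follow-up). A constant post-treatment hazard
#' cannot reproduce that pattern because late deaths are pre-empted by the
#' tumor-size censoring rule.
#'
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   measurement noise on volume (default 0.15; caliper error scales with
#'   tumor size).
#' @param cv between-animal coefficients of variation for `alpha`, `beta`,
#'   `i0` and `gamma` (lognormal around the group means).
#' @param hazard_pre constant death hazard (per day) before treatment.
#' @param p_death_post probability that a treatment-day survivor dies
#'   during follow-up.
#' @param frac_death_early fraction of post-treatment deaths occurring
#'   within `early_window` days of treatment.
#' @param early_window length (days) of the early post-treatment mortality
#'   window.
#' @param treat_volume_mean,treat_volume_cv distribution of the per-animal
#'   true volume at the treatment day (cm^3).
#' @param censor_volume volume (cm^3) at or above which an animal is
#'   euthanized and its series censored.
#' @param latency_floor minimum tumor latency (days).
#' @return A list of hyperparameters, including the `params` mean table.
#' @export
default_hyperparams <- function(noise_cv = 0.15,
                                cv = list(alpha = 0.15, beta = 0.50,
                                          i0 = 0.10, gamma = 0.30),
                                hazard_pre = -log(1 - 0.244) / 31,
                                p_death_post = 0.1348,
                                frac_death_early = 0.8421,
                                early_window = 3,
                                treat_volume_mean = 0.5,
                                treat_volume_cv = 0.20,
                                censor_volume = 2,
                                latency_floor = 5) {
  stopifnot(noise_cv >= 0, all(unlist(cv) >= 0),
            hazard_pre >= 0, p_death_post >= 0, p_death_post < 1,
            frac_death_early >= 0, frac_death_early <= 1,
            treat_volume_mean > 0, censor_volume > 0)
  list(params = group_param_means(), cv = cv, noise_cv = noise_cv,
       hazard_pre = hazard_pre, p_death_post = p_death_post,
       frac_death_early = frac_death_early, early_window = early_window,
       treat_volume_mean = treat_volume_mean,
       treat_volume_cv = treat_volume_cv,
       censor_volume = censor_volume, latency_floor = latency_floor)
}

#' Study design for cohort simulation
#'
#' @param groups a group table as from [default_group_table()].
#' @param treatment_day day post-inoculation at which DC is applied.
#' @param last_day last follow-up day.
#' @param measurement_days caliper-measurement schedule (days
#'   post-inoculation). The default is a twice-weekly schedule of 11 points
#'   spanning days 18-49 and hitting the treatment day exactly.
#' @param seed mandatory integer seed; the cohort is deterministic given it.
#' @return An object of class `"study_design"`.
#' @export
study_design <- function(groups = default_group_table(),
                         treatment_day = 31, last_day = 49,
                         measurement_days = c(18, 21, 24, 27, 31,
                                              34, 37, 40, 43, 46, 49),
                         seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("'seed' is mandatory and must be a single integer")
  }
  measurement_days <- sort(unique(measurement_days))
  if (!(treatment_day %in% measurement_days)) {
    stop("'treatment_day' must be one of the measurement days")
  }
  if (treatment_day >= last_day) stop("'treatment_day' must precede 'last_day'")
  if (any(groups$control & groups$i != 0)) {
    stop("control groups must have i = 0")
  }
  structure(list(groups = groups, treatment_day = treatment_day,
                 last_day = last_day, measurement_days = measurement_days,
                 seed = as.integer(seed)),
            class = "study_design")
}

## mean-preserving lognormal draw; cv = 0 returns the mean exactly
rlnorm_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  s <- sqrt(log(1 + cv^2))
  mean * exp(stats::rnorm(n, -s^2 / 2, s))
}

#' Draw per-animal kinetic parameters
#'
#' Samples one animal's growth and treatment parameters from lognormal
#' (hence strictly positive) distributions around the gender- and
#' group-specific population means; zero dispersion returns the means
#' exactly. Latency is drawn from a normal truncated below at the floor.
#'
#' @param group group label (e.g. `"CG1"`, `"TG2"`).
#' @param gender `"F"` or `"M"`.
#' @param hyper hyperparameters from [default_hyperparams()].
#' @return A list with `alpha`, `beta`, `i0`, `gamma` (NA for controls),
#'   `latency` (days) and `V_treat` (cm^3, true volume at treatment day).
#' @export
sample_animal_params <- function(group, gender, hyper = default_hyperparams()) {
  tab <- hyper$params
  row <- tab[tab$group == group & tab$gender == gender, ]
  if (nrow(row) != 1L) stop("unknown group/gender combination: ", group, "/", gender)
  alpha <- rlnorm_cv(1, row$alpha, hyper$cv$alpha)
  beta  <- rlnorm_cv(1, row$beta, hyper$cv$beta)
  i0 <- gamma <- NA_real_
  if (!is.na(row$i0)) {
    i0    <- rlnorm_cv(1, row$i0, hyper$cv$i0)
    gamma <- rlnorm_cv(1, row$gamma, hyper$cv$gamma)
  }
  latency <- if (row$latency_sd == 0) row$latency_mean else {
    repeat {
      l <- stats::rnorm(1, row$latency_mean, row$latency_sd)
      if (l >= hyper$latency_floor) break
    }
    l
  }
  V_treat <- rlnorm_cv(1, hyper$treat_volume_mean, hyper$treat_volume_cv)
  list(alpha = alpha, beta = beta, i0 = i0, gamma = gamma,
       latency = latency, V_treat = V_treat)
}

## back-solve noisy volumes (cm^3) into major/minor caliper diameters (mm)
## with a stochastic aspect ratio a/b in [1, 2]
volumes_to_diameters <- function(v) {
  rho <- stats::runif(length(v), 1, 2)
  b_cm <- (6 * v / (pi * rho))^(1 / 3)
  data.frame(a_mm = rho * b_cm * 10, b_mm = b_cm * 10)
}

#' Simulate one animal's longitudinal volume series
#'
#' Before treatment the true trajectory follows the unperturbed Gompertz
#' law anchored at the animal's latency day and scaled so that the true
#' volume on the treatment day equals the drawn `V_treat`. From the
#' treatment day onward the trajectory follows the modified Gompertz
#' equation re-anchored at the animal's *observed* (noisy) treatment-day
#' volume, with time re-zeroed at treatment -- mirroring the second-stage
#' initial condition of the fitting protocol. Each scheduled measurement is
#' the model volume times mean-one lognormal noise; caliper diameters are
#' back-solved from the noisy volume. Fate is assigned by two constant
#' death hazards plus deterministic censoring at the ethics volume limit.
#'
#' @param params per-animal parameters from [sample_animal_params()].
#' @param group_row one row of the design's group table.
#' @param gender `"F"` or `"M"`.
#' @param design a [study_design()].
#' @param hyper hyperparameters from [default_hyperparams()].
#' @param animal_id identifier string.
#' @return A `mouse_record`: list with `animal_id`, `group`, `gender`,
#'   `latency`, `true_params`, `observations` (data.frame `day`, `a_mm`,
#'   `b_mm`, `volume_cm3`), `fate`, `fate_day`.
#' @export
simulate_mouse <- function(params, group_row, gender, design,
                           hyper = default_hyperparams(),
                           animal_id = "m1") {
  stopifnot(inherits(design, "study_design"))
  td <- design$treatment_day
  lat <- params$latency
  a <- params$alpha; b <- params$beta

  ## anchor the pre-treatment curve: V(td) = V_treat
  V_lat <- params$V_treat / exp((a / b) * (1 - exp(-b * (td - lat))))
  p_pre <- gompertz_params(V_lat, a, b)

  days <- design$measurement_days[design$measurement_days >= lat]
  pre_days <- days[days <= td]
  post_days <- days[days > td]

  noise <- function(n) {
    if (hyper$noise_cv == 0) return(rep(1, n))
    s <- sqrt(log(1 + hyper$noise_cv^2))
    exp(stats::rnorm(n, -s^2 / 2, s))
  }

  v_pre_true <- gompertz_volume(pre_days - lat, p_pre)
  v_pre_obs <- v_pre_true * noise(length(pre_days))

  ## post-treatment model anchored at the observed treatment-day volume.
  ## Treated animals follow the treatment model, whose clock starts at the
  ## moment of current application; control animals simply continue their
  ## own Gompertz trajectory (no treatment event, no kink).
  v_post_obs <- numeric(0)
  if (length(post_days) && td %in% pre_days) {
    V0_post <- v_pre_obs[pre_days == td]
    i_app <- group_row$i
    if (i_app > 0) {
      e <- echt_params(i_app, params$i0, params$gamma)
      p_post <- gompertz_params(V0_post, a, b)
      v_post_true <- mge_volume(post_days - td, p_post, e)
    } else {
      v_post_true <- V0_post * exp((a / b) * (exp(-b * (td - lat)) -
                                                exp(-b * (post_days - lat))))
    }
    v_post_obs <- v_post_true * noise(length(post_days))
  } else {
    post_days <- numeric(0)
  }

  obs_days <- c(pre_days, post_days)
  obs_v <- c(v_pre_obs, v_post_obs)

  ## fate: earlier of pre-/post-treatment death and the censoring rule
  fate <- "completed"
  fate_day <- design$last_day
  t_die_pre <- if (hyper$hazard_pre > 0) stats::rexp(1, hyper$hazard_pre) else Inf
  t_die_post <- Inf
  if (hyper$p_death_post > 0 && stats::runif(1) < hyper$p_death_post) {
    t_die_post <- td + if (stats::runif(1) < hyper$frac_death_early) {
      stats::runif(1, 0, hyper$early_window)
    } else {
      stats::runif(1, hyper$early_window, design$last_day - td)
    }
  }
  death_day <- if (t_die_pre < td) t_die_pre else t_die_post
  censor_day <- Inf
  hit <- which(obs_v >= hyper$censor_volume)
  if (length(hit)) censor_day <- obs_days[hit[1]]

  if (death_day <= design$last_day && death_day < censor_day) {
    fate <- if (death_day < td) "died_pre_treatment" else "died_post_treatment"
    fate_day <- death_day
    keep <- obs_days < death_day
  } else if (is.finite(censor_day)) {
    fate <- "censored_large_tumor"
    fate_day <- censor_day
    keep <- obs_days <= censor_day  # the triggering measurement is retained
  } else {
    keep <- rep(TRUE, length(obs_days))
  }
  obs_days <- obs_days[keep]; obs_v <- obs_v[keep]

  dm <- volumes_to_diameters(obs_v)
  obs <- data.frame(day = obs_days, a_mm = dm$a_mm, b_mm = dm$b_mm,
                    volume_cm3 = obs_v)
  list(animal_id = animal_id, group = group_row$group, gender = gender,
       latency = lat,
       true_params = params,
       observations = obs, fate = fate, fate_day = fate_day)
}

#' Simulate a full cohort
#'
#' Draws every animal of the design (all groups, both genders) and returns
#' both the per-animal records and a flat long-format table. The result is
#' a deterministic function of the design seed.
#'
#' @param design a [study_design()].
#' @param hyper hyperparameters from [default_hyperparams()].
#' @return A list with `records` (list of mouse records) and `table`
#'   (data.frame with columns `animal_id`, `group`, `gender`, `day`,
#'   `a_mm`, `b_mm`, `volume_cm3`, `fate`).
#' @export
#' @examples
#' design <- study_design(seed = 1)
#' cohort <- simulate_cohort(design)
#' head(cohort$table)
simulate_cohort <- function(design, hyper = default_hyperparams()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  records <- list()
  for (gi in seq_len(nrow(design$groups))) {
    grow <- design$groups[gi, ]
    for (gender in c("F", "M")) {
      for (k in seq_len(grow$n_per_gender)) {
        id <- sprintf("%s-%s-%02d", grow$group, gender, k)
        ap <- sample_animal_params(grow$group, gender, hyper)
        records[[id]] <- simulate_mouse(ap, grow, gender, design, hyper, id)
      }
    }
  }
  ids <- vapply(records, `[[`, "", "animal_id")
  if (anyDuplicated(ids)) stop("duplicate animal ids generated")
  tabs <- lapply(records, function(r) {
    if (nrow(r$observations) == 0) return(NULL)
    cbind(animal_id = r$animal_id, group = r$group, gender = r$gender,
          r$observations, fate = r$fate, stringsAsFactors = FALSE)
  })
  tab <- rbind_rows(tabs)
  list(records = records, table = tab)
}

#' Ellipsoid volume from caliper diameters
#'
#' Converts major/minor caliper diameters in millimeters to tumor volume in
#' cm^3 via \eqn{V = \pi a b^2 / 6} (diameters converted mm to cm first).
#'
#' @param a_mm major diameter (mm); must satisfy `a_mm >= b_mm`.
#' @param b_mm minor diameter (mm), > 0.
#' @return Volume(s) in cm^3.
#' @export
#' @examples
#' diameters_to_volume(10, 10)  # ~0.5236 cm^3
diameters_to_volume <- function(a_mm, b_mm) {
  if (any(b_mm <= 0)) stop("'b_mm' must be > 0")
  if (any(a_mm < b_mm)) stop("major diameter smaller than minor: swapped arguments?")
  pi * (a_mm / 10) * (b_mm / 10)^2 / 6
}

#' Attrition rates from cohort counts
#'
#' Bookkeeping on study attrition: the percentage of animals dying before
#' treatment, the percentage of treatment-day survivors dying during
#' follow-up, and the percentage of the initial cohort that is evaluable
#' (survived the whole study).
#'
#' @param n_initial number of animals enrolled.
#' @param died_pre number dying before the treatment day.
#' @param died_post number dying after treatment.
#' @return A list with `pre_treatment_death_percent`,
#'   `post_treatment_death_percent` (denominator: treatment-day survivors)
#'   and `evaluable_percent`.
#' @export
#' @examples
#' attrition_rates(160, 39, 19)
attrition_rates <- function(n_initial, died_pre, died_post) {
  stopifnot(n_initial > 0, died_pre >= 0, died_post >= 0,
            died_pre + died_post <= n_initial)
  at_treatment <- n_initial - died_pre
  list(
    pre_treatment_death_percent = 100 * died_pre / n_initial,
    post_treatment_death_percent = if (at_treatment > 0)
      100 * died_post / at_treatment else NA_real_,
    evaluable_percent = 100 * (n_initial - died_pre - died_post) / n_initial
  )
}

#' Attrition rates of a simulated cohort
#'
#' @param cohort result of [simulate_cohort()].
#' @return As [attrition_rates()], computed from the cohort's fate labels.
#' @export
cohort_attrition <- function(cohort) {
  fates <- vapply(cohort$records, `[[`, "", "fate")
  attrition_rates(length(fates),
                  sum(fates == "died_pre_treatment"),
                  sum(fates == "died_post_treatment"))
}
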