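# Synthetic EHR-like PV cohort generator with planted hazard structure.

#' Default marginal targets for the development-like cohort
#'
#' Median and quartiles emulating a US EHR-derived PV population on
#' hydroxyurea. Laboratory targets: NEP 70 (62--78) \%, LYP 19.5 (13--26.3) \%,
#' RDW 17.0 (14.5--19.3) \%, WBC 7.7 (5.9--10.3) 10^9/L, Hct 43 (39.7--46.3)
#' \%, HGB 140 (130--151) g/L, Plt 278 (203--381) 10^9/L; age 73 (64--80)
#' years. Observation targets (BMI, blood pressures, weight, height, heart
#' rate, respiration, pulse) are typical values for an elderly US population
#' and are the generator's own choices.
#'
#' @return Named list of `c(median, q25, q75)` per variable.
#' @export
default_marginals <- function() {
  list(
    NEP = c(70, 62, 78), LYP = c(19.5, 13.0, 26.3), RDW = c(17.0, 14.5, 19.3),
    WBC = c(7.7, 5.9, 10.3), Hct = c(43, 39.7, 46.3), HGB = c(140, 130, 151),
    Plt = c(278, 203, 381),
    BMI = c(28, 24.5, 32), DBP = c(76, 70, 83), SBP = c(128, 118, 139),
    weight = c(82, 70, 95), height = c(170, 163, 178), HRT = c(76, 68, 85),
    RSP = c(16, 14, 18), PLS = c(76, 68, 85),
    age = c(73, 64, 80)
  )
}

#' @rdname default_marginals
#' @details `croatian_marginals()` targets the smaller registry-like
#'   validation population: NEP 68 (60--78), LYP 22 (14.8--30), RDW 16.0
#'   (14.3--17.5), WBC 7.2 (6.0--11.7), Hct 42 (40--46), HGB 144 (129--154),
#'   Plt 269 (200--454), age 65 (56--72).
#' @export
croatian_marginals <- function() {
  m <- default_marginals()
  m$NEP <- c(68, 60, 78); m$LYP <- c(22, 14.8, 30); m$RDW <- c(16.0, 14.3, 17.5)
  m$WBC <- c(7.2, 6.0, 11.7); m$Hct <- c(42, 40, 46); m$HGB <- c(144, 129, 154)
  m$Plt <- c(269, 200, 454); m$age <- c(65, 56, 72)
  m
}

#' Default planted threshold interactions
#'
#' Two quadrant effects on the post-index TE hazard: NEP >= 72.05 \% combined
#' with RDW < 14.3 \%, and LYP < 19.3 \% combined with RDW < 14.05 \%, each
#' multiplying the hazard by `exp(log_hr)` for patients inside the quadrant.
#'
#' @param log_hr log hazard ratio applied inside each quadrant.
#' @return Data frame with one row per interaction.
#' @export
default_interactions <- function(log_hr = 1.8) {
  data.frame(
    var1 = c("NEP", "LYP"), threshold1 = c(72.05, 19.3),
    direction1 = c(">=", "<"),
    var2 = c("RDW", "RDW"), threshold2 = c(14.3, 14.05),
    direction2 = c("<", "<"),
    log_hr = rep(log_hr, 2),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: marginal lab and
#' observation distributions (log-normal, solved from median/IQR targets), a
#' negative NEP--LYP correlation through a shared Gaussian copula, binary
#' risk-factor prevalences, and a proportional-hazards TE process with planted
#' main effects and threshold-quadrant interactions. Censoring combines an
#' administrative record end with exponential dropout. All hazards are per
#' patient-year.
#'
#' @param n_patients cohort size.
#' @param seed integer seed; `NULL` leaves the RNG state untouched.
#' @param marginals named list of `c(median, q25, q75)` targets (must include
#'   `age` and all of [pv_lab_vars]/[pv_obs_vars]).
#' @param te_history_prevalence,female_fraction,anticoag_prevalence,smoking_prevalence,alcohol_prevalence
#'   binary prevalences in \[0,1\].
#' @param mf_et_rate,other_cytoreductive_rate prevalence of the exclusion
#'   flags.
#' @param switch_fraction fraction of patients who switch from HU to
#'   ruxolitinib.
#' @param baseline_hazard baseline TE hazard (events per patient-year).
#' @param effects named log hazard ratios: `te_history`, `anticoag`,
#'   `age_per_decade` (centred at age 73).
#' @param interactions data frame as from [default_interactions()].
#' @param nep_lyp_rho Gaussian-copula correlation between NEP and LYP latents.
#' @param dropout_rate exponential dropout hazard (per patient-year).
#' @param lab_block_missing_rate,obs_block_missing_rate probability that a
#'   patient has no lab (resp. observation) medians at all.
#' @param item_missing_rate per-variable missingness for the remaining
#'   patients.
#' @param pre_index_range,admin_followup_range day ranges for the pre-index
#'   record length and the administrative follow-up after index.
#' @param label provenance label attached to generated cohorts.
#' @return An object of class `pv_gen_config`.
#' @export
generator_config <- function(n_patients = 2000,
                             seed = NULL,
                             marginals = default_marginals(),
                             te_history_prevalence = 0.161,
                             female_fraction = 0.51,
                             anticoag_prevalence = 0.48,
                             smoking_prevalence = 0.128,
                             alcohol_prevalence = 0.25,
                             mf_et_rate = 0.05,
                             other_cytoreductive_rate = 0.03,
                             switch_fraction = 0,
                             baseline_hazard = 0.06,
                             effects = c(te_history = 2.2, anticoag = 0.4,
                                         age_per_decade = 0.5),
                             interactions = default_interactions(),
                             nep_lyp_rho = -0.8,
                             dropout_rate = 0.05,
                             lab_block_missing_rate = 0.07,
                             obs_block_missing_rate = 0.05,
                             item_missing_rate = 0.03,
                             pre_index_range = c(365, 2500),
                             admin_followup_range = c(550, 2200),
                             label = "synthetic-ehr") {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("n_patients must be a positive count")
  }
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  probs <- c(te_history_prevalence, female_fraction, anticoag_prevalence,
             smoking_prevalence, alcohol_prevalence, mf_et_rate,
             other_cytoreductive_rate, switch_fraction,
             lab_block_missing_rate, obs_block_missing_rate,
             item_missing_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (dropout_rate < 0) stop("dropout_rate must be >= 0")
  need <- c(pv_lab_vars, pv_obs_vars, "age")
  if (!all(need %in% names(marginals))) {
    stop("marginals must define: ", paste(need, collapse = ", "))
  }
  if (nrow(interactions) > 0) {
    known <- c(pv_lab_vars, pv_obs_vars, "age_at_index")
    vars <- c(interactions$var1, interactions$var2)
    if (!all(vars %in% known)) {
      stop("interaction references unknown variable(s): ",
           paste(setdiff(vars, known), collapse = ", "))
    }
    if (any(c(interactions$threshold1, interactions$threshold2) <= 0)) {
      stop("interaction thresholds must be positive")
    }
  }
  cfg <- as.list(environment())
  structure(cfg, class = "pv_gen_config")
}

#' @rdname generator_config
#' @details `validation_config()` switches the defaults to the registry-like
#'   validation population (n = 100, TE-history prevalence 0.32, Croatian
#'   marginals, higher anticoagulant use) while keeping the same planted
#'   interaction thresholds, so fixed-threshold validation has signal to find.
#' @export
validation_config <- function(n_patients = 100, seed = NULL, ...) {
  generator_config(n_patients = n_patients, seed = seed,
                   marginals = croatian_marginals(),
                   te_history_prevalence = 0.32,
                   female_fraction = 0.45,
                   anticoag_prevalence = 0.81,
                   smoking_prevalence = 0.17,
                   label = "synthetic-validation", ...)
}

# log-normal parameters from a (median, q25, q75) target
lognormal_sigma <- function(target) {
  log(target[3] / target[2]) / (2 * stats::qnorm(0.75))
}

# N(mean, sd) truncated to [lo, hi] via inverse-CDF sampling
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# event times of an inhomogeneous-rate-free Poisson process on [0, horizon),
# per-subject constant rate (per day); gap exponentials are drawn in one fixed
# block so that, for a common seed, raising a rate only rescales the same
# uniforms (common random numbers), topping up the rare rows that overflow
poisson_process_times <- function(rate_per_day, horizon) {
  n <- length(rate_per_day)
  k0 <- 50L
  gaps <- matrix(stats::rexp(n * k0), nrow = n)
  times <- lapply(seq_len(n), function(i) {
    if (rate_per_day[i] <= 0 || horizon[i] <= 0) return(numeric(0))
    g <- cumsum(gaps[i, ] / rate_per_day[i])
    while (g[length(g)] < horizon[i]) {
      g <- c(g, g[length(g)] + cumsum(stats::rexp(k0) / rate_per_day[i]))
    }
    g[g < horizon[i]]
  })
  times
}

#' Generate a synthetic PV cohort
#'
#' Draws a cohort with the statistical structure the downstream analyses
#' assume: skewed lab/observation marginals matching the configured
#' median/IQR targets, a negative NEP--LYP correlation, and TE event times
#' from a constant-hazard (exponential) process whose rate is
#' `baseline_hazard * exp(planted effects)`. The planted effects comprise the
#' TE-history, anticoagulant and age main effects plus the configured
#' threshold-quadrant interactions; pre-index events use only the TE-history
#' effect (labs describe the post-index window). Censoring is administrative
#' at `record_end`, which already reflects exponential dropout. Reproducible
#' for a fixed seed. The full configuration (the ground truth) is attached as
#' attribute `"truth"`.
#'
#' @param config a [generator_config()].
#' @return A [pv_cohort] with eligibility-flag columns (`has_mf_et`,
#'   `has_other_cytoreductive`, `n_hu_prescriptions`, `n_rux_prescriptions`).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "pv_gen_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- as.integer(config$n_patients)
  m <- config$marginals

  # continuous marginals: shared latent copula for NEP/LYP, the rest
  # independent; value = median * exp(sigma * z)
  z_nep <- stats::rnorm(n)
  z_lyp <- config$nep_lyp_rho * z_nep +
    sqrt(1 - config$nep_lyp_rho^2) * stats::rnorm(n)
  cont <- list()
  for (v in c(pv_lab_vars, pv_obs_vars)) {
    z <- switch(v, NEP = z_nep, LYP = z_lyp, stats::rnorm(n))
    cont[[v]] <- m[[v]][1] * exp(lognormal_sigma(m[[v]]) * z)
  }
  age <- rtruncnorm(n, m$age[1], (m$age[3] - m$age[2]) / (2 * stats::qnorm(0.75)),
                    18, 100)

  te_history <- stats::runif(n) < config$te_history_prevalence
  sex <- ifelse(stats::runif(n) < config$female_fraction, "F", "M")
  anticoag <- stats::runif(n) < config$anticoag_prevalence
  smoking <- stats::runif(n) < config$smoking_prevalence
  alcohol <- stats::runif(n) < config$alcohol_prevalence
  race <- sample(c("White", "Black", "Asian", "Other"), n, replace = TRUE,
                 prob = c(0.78, 0.10, 0.04, 0.08))
  region <- sample(c("Midwest", "Northeast", "South", "West"), n,
                   replace = TRUE, prob = c(0.30, 0.25, 0.30, 0.15))
  n_phlebotomy <- stats::rpois(n, 1.5)

  # timeline: integer day offsets, index fixed at day 1000
  index <- rep(1000L, n)
  pre_len <- round(stats::runif(n, config$pre_index_range[1],
                                config$pre_index_range[2]))
  record_start <- index - pre_len
  admin <- stats::runif(n, config$admin_followup_range[1],
                        config$admin_followup_range[2])
  dropout <- if (config$dropout_rate > 0) {
    stats::rexp(n, config$dropout_rate / DAYS_PER_YEAR)
  } else {
    rep(Inf, n)
  }
  record_end <- index + floor(pmin(admin, dropout))

  # treatment course
  switcher <- stats::runif(n) < config$switch_fraction
  hu_first <- index
  hu_dur <- round(stats::runif(n, 200, 1500))
  rux_first <- ifelse(switcher, index + round(stats::runif(n, 180, 600)),
                      NA_real_)
  rux_last <- ifelse(switcher,
                     pmin(rux_first + round(stats::runif(n, 180, 900)),
                          record_end),
                     NA_real_)
  switcher <- switcher & !is.na(rux_first) & rux_first < record_end
  rux_first[!switcher] <- NA_real_
  rux_last[!switcher] <- NA_real_
  hu_last <- pmin(index + hu_dur, record_end)
  hu_last <- ifelse(switcher, pmin(hu_last, rux_first), hu_last)
  n_hu <- 2L + stats::rpois(n, 6)
  n_rux <- ifelse(switcher, 2L + stats::rpois(n, 4), 0L)

  # planted proportional-hazards structure (per day, from index onward)
  eff <- config$effects
  lp <- eff[["te_history"]] * te_history + eff[["anticoag"]] * anticoag +
    eff[["age_per_decade"]] * (age - 73) / 10
  if (nrow(config$interactions) > 0) {
    for (i in seq_len(nrow(config$interactions))) {
      ia <- config$interactions[i, ]
      g1 <- get_interaction_var(cont, age, ia$var1)
      g2 <- get_interaction_var(cont, age, ia$var2)
      inside <- apply_direction(g1, ia$threshold1, ia$direction1) &
        apply_direction(g2, ia$threshold2, ia$direction2)
      lp <- lp + ia$log_hr * inside
    }
  }
  rate_post <- config$baseline_hazard * exp(lp) / DAYS_PER_YEAR
  rate_pre <- config$baseline_hazard * exp(eff[["te_history"]] * te_history) /
    DAYS_PER_YEAR
  post_events <- poisson_process_times(rate_post, record_end - index)
  pre_events <- poisson_process_times(rate_pre, index - record_start)
  te_times <- lapply(seq_len(n), function(i) {
    tt <- c(record_start[i] + pre_events[[i]], index[i] + post_events[[i]])
    unique(round(sort(tt)))
  })

  # missingness: whole-block absence (no labs taken at all) plus sporadic
  # per-item gaps; absence is meaningful and handled by eligibility filtering
  lab_block <- stats::runif(n) < config$lab_block_missing_rate
  obs_block <- stats::runif(n) < config$obs_block_missing_rate
  for (v in pv_lab_vars) {
    drop <- lab_block | stats::runif(n) < config$item_missing_rate
    cont[[v]][drop] <- NA_real_
  }
  for (v in pv_obs_vars) {
    drop <- obs_block | stats::runif(n) < config$item_missing_rate
    cont[[v]][drop] <- NA_real_
  }

  df <- data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    age_at_index = age, sex = sex, race = race, region = region,
    te_history = te_history, n_phlebotomy = n_phlebotomy,
    anticoag_antiplatelet = anticoag, smoking = smoking, alcohol = alcohol,
    stringsAsFactors = FALSE
  )
  for (v in c(pv_lab_vars, pv_obs_vars)) df[[v]] <- cont[[v]]
  df$index_date <- index
  df$hu_first <- hu_first
  df$hu_last <- hu_last
  df$rux_first <- rux_first
  df$rux_last <- rux_last
  df$record_start <- record_start
  df$record_end <- record_end
  df$te_times <- te_times
  df$has_mf_et <- stats::runif(n) < config$mf_et_rate
  df$has_other_cytoreductive <- stats::runif(n) < config$other_cytoreductive_rate
  df$n_hu_prescriptions <- n_hu
  df$n_rux_prescriptions <- n_rux

  out <- pv_cohort(df, label = config$label)
  attr(out, "truth") <- config
  out
}

get_interaction_var <- function(cont, age, name) {
  if (name == "age_at_index") age else cont[[name]]
}

apply_direction <- function(x, threshold, direction) {
  switch(direction,
         ">=" = x >= threshold,
         "<" = x < threshold,
         ">" = x > threshold,
         "<=" = x <= threshold,
         stop("unknown direction: ", direction))
}

#' Generate a registry-like validation cohort
#'
#' Convenience wrapper around [generate_cohort()] with [validation_config()]
#' defaults: a small cohort (n = 100 by default) with the validation-population
#' marginals and TE-history prevalence, but the same planted interaction
#' thresholds as the development cohort, so that fixed-threshold external
#' validation has a real signal to detect.
#'
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @param ... further arguments passed to [validation_config()].
#' @return A [pv_cohort].
#' @export
generate_validation_cohort <- function(n_patients = 100, seed = NULL, ...) {
  generate_cohort(validation_config(n_patients = n_patients, seed = seed, ...))
}
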