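#' Field names of one phase's utilization block
#'
#' Each patient record carries these quantities once per 6-month phase,
#' prefixed `a_` (oral-antipsychotic phase) and `b_` (aripiprazole-depot
#' phase) in the flat cohort table.
#'
#' @return Character vector of the 16 field names.
#' @export
utilization_fields <- function() {
  c("episodes", "hospitalizations", "hospital_days", "day_clinic_days",
    "psychiatrist_visits", "emergency_service_contacts",
    "emergency_physician_contacts", "sick_leave_days",
    "ebm_outpatient_eur", "goa_outpatient_eur", "ebm_inpatient_eur",
    "goa_inpatient_eur", "non_drug_eur", "medication_eur",
    "comorbid_medication_eur", "depot_injections")
}

#' Per-phase calibration targets
#'
#' Targets the generator reproduces in expectation for one phase. Means for
#' hospitalizations, hospital days, day-clinic days, episodes and sick-leave
#' days are unconditional (per patient, or per employed patient for sick
#' leave); emergency-contact means are conditional on having at least one
#' contact, paired with an occurrence rate, because that is how they are
#' reported. Monetary fields are unconditional mean euro amounts with a
#' common coefficient of variation; inpatient fee amounts are drawn only for
#' hospitalized patients.
#'
#' @param hospitalization_rate probability of >= 1 psychiatric
#'   hospitalization in the phase.
#' @param hospitalization_mean unconditional mean number of hospitalizations.
#' @param hospital_days_mean,hospital_days_sd unconditional moments of
#'   hospitalized days.
#' @param day_clinic_rate probability of any day-clinic/PIA use.
#' @param day_clinic_mean,day_clinic_sd unconditional moments of
#'   day-clinic/PIA days.
#' @param episodes_mean,episodes_sd moments of schizophrenia episodes
#'   (negative-binomial when overdispersed).
#' @param psychiatrist_visits_mean mean psychiatrist visits (Poisson).
#' @param emergency_service_rate,emergency_service_mean occurrence rate and
#'   conditional mean of emergency-service contacts.
#' @param emergency_physician_rate,emergency_physician_mean same for
#'   emergency-physician contacts.
#' @param sick_leave_rate probability that an employed patient has any sick
#'   leave in the phase.
#' @param sick_leave_mean,sick_leave_sd unconditional moments of sick-leave
#'   days over the employed stratum.
#' @param ebm_outpatient_mean,goa_outpatient_mean,ebm_inpatient_mean,goa_inpatient_mean,non_drug_mean,medication_mean,comorbid_medication_mean
#'   unconditional mean euro amounts per patient.
#' @param depot_injections_mean mean number of depot injections (0 in the
#'   oral phase; drawn as binomial out of 6 injection opportunities).
#' @param money_cv coefficient of variation of the log-normal euro amounts.
#' @return A named list of class `phase_targets`.
#' @export
phase_targets <- function(hospitalization_rate, hospitalization_mean,
                          hospital_days_mean, hospital_days_sd,
                          day_clinic_rate, day_clinic_mean, day_clinic_sd,
                          episodes_mean, episodes_sd,
                          psychiatrist_visits_mean,
                          emergency_service_rate, emergency_service_mean,
                          emergency_physician_rate, emergency_physician_mean,
                          sick_leave_rate, sick_leave_mean, sick_leave_sd,
                          ebm_outpatient_mean, goa_outpatient_mean,
                          ebm_inpatient_mean, goa_inpatient_mean,
                          non_drug_mean, medication_mean,
                          comorbid_medication_mean,
                          depot_injections_mean = 0,
                          money_cv = 1) {
  x <- as.list(environment())
  rates <- c("hospitalization_rate", "day_clinic_rate",
             "emergency_service_rate", "emergency_physician_rate",
             "sick_leave_rate")
  for (nm in rates) {
    if (x[[nm]] < 0 || x[[nm]] > 1) {
      abort(paste0("invalid phase target ", nm, ": must be in [0, 1]"),
            class = "switchbia_config_error")
    }
  }
  for (nm in names(x)) {
    if (x[[nm]] < 0) {
      abort(paste0("invalid phase target ", nm, ": must be >= 0"),
            class = "switchbia_config_error")
    }
  }
  structure(x, class = "phase_targets")
}

default_phase_a <- function() {
  phase_targets(
    hospitalization_rate = 0.551, hospitalization_mean = 0.63,
    hospital_days_mean = 27.39, hospital_days_sd = 41.37,
    day_clinic_rate = 0.60, day_clinic_mean = 46.13, day_clinic_sd = 45.47,
    episodes_mean = 2.58, episodes_sd = 2.91,
    psychiatrist_visits_mean = 10.57,
    # conditional contact means as reported; occurrence rates recovered from
    # per-case cost / unit rate / conditional mean
    emergency_service_rate = 0.098486, emergency_service_mean = 2.38,
    emergency_physician_rate = 0.053030, emergency_physician_mean = 1.42,
    sick_leave_rate = 0.70, sick_leave_mean = 40.06, sick_leave_sd = 29.62,
    ebm_outpatient_mean = 314.37, goa_outpatient_mean = 28.64,
    ebm_inpatient_mean = 78.36, goa_inpatient_mean = 4.67,
    non_drug_mean = 373.42, medication_mean = 2447.80,
    comorbid_medication_mean = 461.07,
    depot_injections_mean = 0
  )
}

default_phase_b <- function() {
  phase_targets(
    hospitalization_rate = 0.14, hospitalization_mean = 0.16,
    hospital_days_mean = 5.56, hospital_days_sd = 20.70,
    day_clinic_rate = 0.25, day_clinic_mean = 7.29, day_clinic_sd = 15.02,
    episodes_mean = 0.41, episodes_sd = 0.76,
    psychiatrist_visits_mean = 7.73,
    emergency_service_rate = 0.022727, emergency_service_mean = 2.00,
    emergency_physician_rate = 0.003788, emergency_physician_mean = 2.00,
    sick_leave_rate = 0.35, sick_leave_mean = 15.80, sick_leave_sd = 24.67,
    ebm_outpatient_mean = 286.18, goa_outpatient_mean = 11.98,
    ebm_inpatient_mean = 26.02, goa_inpatient_mean = 1.29,
    non_drug_mean = 103.79, medication_mean = 103.35,
    comorbid_medication_mean = 238.07,
    depot_injections_mean = 2325.57 / 515.97
  )
}

#' Cohort generator configuration
#'
#' Default values reproduce the switch study's conditions: 132 patients,
#' two 6-month phases (183 days each), employment distribution
#' 24/39/51/9/9 (employed/unemployed/retired/education/unknown), and the
#' reported phase-wise utilization moments.
#'
#' @param n cohort size (default 132).
#' @param seed integer seed; all randomness of [generate_cohort()] flows
#'   from it.
#' @param phase_a,phase_b [phase_targets()] for the oral and depot phases.
#' @param employment named counts or proportions over
#'   employed/unemployed/retired/education/unknown.
#' @param frailty_correlation correlation in \[0, 1\] of the shared
#'   per-patient latent that couples utilization across phases and
#'   quantities (a Gaussian-copula patient frailty; marginals are
#'   unaffected).
#' @param missingness probability that any single count/day quantity is
#'   item-nonresponse (`NA`); default 0.
#' @param phase_length_days observation window per phase (day caps).
#' @param demographics list of moments: `age_mean`, `age_sd`,
#'   `female_share`, `age_dx_mean`, `age_dx_sd`, `statutory_share`,
#'   `copay_exempt_share`.
#' @return A `cohort_config` object.
#' @examples
#' cfg <- cohort_config(n = 20, seed = 7)
#' nrow(generate_cohort(cfg))
#' @export
cohort_config <- function(n = 132, seed = 20160501,
                          phase_a = default_phase_a(),
                          phase_b = default_phase_b(),
                          employment = c(employed = 24, unemployed = 39,
                                         retired = 51, education = 9,
                                         unknown = 9),
                          frailty_correlation = 0.4,
                          missingness = 0,
                          phase_length_days = 183,
                          demographics = list(
                            age_mean = 37.81, age_sd = 10.54,
                            female_share = 71 / 131,
                            age_dx_mean = 30.55, age_dx_sd = 8.67,
                            statutory_share = 122 / 132,
                            copay_exempt_share = 72 / 122
                          )) {
  if (!is.numeric(n) || n < 1) {
    abort("invalid config field n: must be >= 1",
          class = "switchbia_config_error")
  }
  if (frailty_correlation < 0 || frailty_correlation > 1) {
    abort("invalid config field frailty_correlation: must be in [0, 1]",
          class = "switchbia_config_error")
  }
  if (missingness < 0 || missingness >= 1) {
    abort("invalid config field missingness: must be in [0, 1)",
          class = "switchbia_config_error")
  }
  if (phase_length_days <= 0) {
    abort("invalid config field phase_length_days: must be > 0",
          class = "switchbia_config_error")
  }
  need <- c("employed", "unemployed", "retired", "education", "unknown")
  if (!all(need %in% names(employment)) || any(employment < 0) ||
      sum(employment) <= 0) {
    abort("invalid config field employment: need non-negative weights for employed/unemployed/retired/education/unknown",
          class = "switchbia_config_error")
  }
  stopifnot(inherits(phase_a, "phase_targets"),
            inherits(phase_b, "phase_targets"))
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         phase_a = phase_a, phase_b = phase_b,
         employment = employment / sum(employment),
         frailty_correlation = frailty_correlation,
         missingness = missingness,
         phase_length_days = phase_length_days,
         demographics = demographics),
    class = "cohort_config"
  )
}

# log-normal parameters matched to a target mean/sd; when a cap is given the
# meanlog is adjusted so that E[min(X, cap)] equals the target mean (days are
# censored at the phase length, so matching the raw distribution would bias
# the calibrated mean downward).
lnorm_match <- function(mean, sd, cap = Inf) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  if (is.finite(cap)) {
    if (mean >= cap) {
      abort("target mean exceeds the phase-length cap",
            class = "switchbia_config_error")
    }
    cens_mean <- function(ml) {
      exp(ml + sdlog^2 / 2) * pnorm((log(cap) - ml - sdlog^2) / sdlog) +
        cap * (1 - pnorm((log(cap) - ml) / sdlog))
    }
    if (cens_mean(meanlog) < mean) {
      meanlog <- uniroot(function(ml) cens_mean(ml) - mean,
                         lower = meanlog, upper = meanlog + 20,
                         tol = 1e-12)$root
    }
  }
  list(meanlog = meanlog, sdlog = sdlog)
}

# zero-truncated Poisson rate with target conditional mean m >= 1
ztp_lambda <- function(m) {
  if (m < 1) {
    abort("conditional count mean below 1 is infeasible for a zero-truncated Poisson",
          class = "switchbia_config_error")
  }
  if (m == 1) return(1e-9)
  uniroot(function(l) l / (1 - exp(-l)) - m,
          lower = 1e-9, upper = max(2 * m, 1), tol = 1e-12)$root
}

q_ztp <- function(u, lambda) {
  p0 <- ppois(0, lambda)
  qpois(p0 + u * (1 - p0), lambda)
}

# conditional (given any use) moments from unconditional mean/sd and use rate
conditional_moments <- function(mean, sd, rate, what) {
  if (rate <= 0 || mean == 0) return(NULL)
  m_c <- mean / rate
  v_c <- (sd^2 + mean^2) / rate - m_c^2
  if (v_c < 0) {
    abort(paste0("invalid config field ", what,
                 ": use rate too low for the requested mean/sd"),
          class = "switchbia_config_error")
  }
  list(mean = m_c, sd = sqrt(v_c))
}

#' Generate a calibrated synthetic cohort
#'
#' Draws `n` patient records with two phase-utilization blocks whose
#' expected values match the configured targets. Occurrence indicators are
#' Bernoulli; counts conditional on occurrence are zero-truncated Poisson;
#' day quantities conditional on any use are log-normal, moment-matched
#' under censoring at the phase length; episodes are negative-binomial;
#' euro amounts are log-normal. A per-patient standard-normal latent is
#' combined with quantity-specific noise (weight
#' `sqrt(frailty_correlation)`) and mapped through a Gaussian copula, so a
#' frail patient is high-utilizing in both phases while every marginal
#' distribution — and hence every calibrated moment — is untouched.
#'
#' @param config a [cohort_config()].
#' @return Tibble, one row per patient: `patient_id`, demographics, and the
#'   [utilization_fields()] prefixed `a_`/`b_`. Identical config (incl.
#'   seed) gives an identical table; the caller's RNG state is preserved.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  n <- config$n
  rho <- config$frailty_correlation
  cap <- config$phase_length_days
  dem <- config$demographics

  # demographics ------------------------------------------------------------
  trunc_norm <- function(u, mean, sd, lo, hi) {
    p_lo <- pnorm(lo, mean, sd); p_hi <- pnorm(hi, mean, sd)
    qnorm(p_lo + u * (p_hi - p_lo), mean, sd)
  }
  age <- round(trunc_norm(runif(n), dem$age_mean, dem$age_sd, 18, 65), 1)
  sex <- ifelse(runif(n) < dem$female_share, "female", "male")
  employment <- sample(names(config$employment), n, replace = TRUE,
                       prob = config$employment)
  insurance <- ifelse(runif(n) < dem$statutory_share, "statutory", "private")
  copay_exempt <- insurance == "statutory" &
    runif(n) < dem$copay_exempt_share
  age_dx <- round(trunc_norm(runif(n), dem$age_dx_mean, dem$age_dx_sd,
                             10, pmin(age, 65)), 1)

  latent <- rnorm(n)   # shared patient frailty (copula scale)
  cop_u <- function() pnorm(sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n))

  draw_phase <- function(tg, prefix) {
    out <- list()
    zero <- numeric(n)

    # hospitalization occurrence drives hospitalizations, hospital days and
    # inpatient fee amounts, guaranteeing days > 0 => hospitalizations >= 1
    u_h <- cop_u()
    occ_h <- if (tg$hospitalization_rate > 0) u_h < tg$hospitalization_rate
             else rep(FALSE, n)
    hosp <- zero
    if (tg$hospitalization_mean > 0 && tg$hospitalization_rate > 0) {
      lam <- ztp_lambda(tg$hospitalization_mean / tg$hospitalization_rate)
      hosp[occ_h] <- q_ztp(u_h[occ_h] / tg$hospitalization_rate, lam)
    }
    out$hospitalizations <- hosp

    # conditional severities reuse the occurrence channel's uniform rescaled
    # by the rate: given occurrence (u < rate), u/rate is exactly uniform, so
    # calibrated conditional moments are preserved; severity is comonotone
    # with occurrence depth within the channel
    days <- zero
    cm <- conditional_moments(tg$hospital_days_mean, tg$hospital_days_sd,
                              tg$hospitalization_rate, "hospital_days")
    if (!is.null(cm)) {
      lp <- lnorm_match(cm$mean, cm$sd, cap)
      u_c <- u_h[occ_h] / tg$hospitalization_rate
      days[occ_h] <- pmin(round(qlnorm(u_c, lp$meanlog, lp$sdlog)), cap)
    }
    out$hospital_days <- days

    dc <- zero
    cm <- conditional_moments(tg$day_clinic_mean, tg$day_clinic_sd,
                              tg$day_clinic_rate, "day_clinic_days")
    u_dc <- cop_u()
    if (!is.null(cm)) {
      lp <- lnorm_match(cm$mean, cm$sd, cap)
      occ <- u_dc < tg$day_clinic_rate
      dc[occ] <- pmin(round(qlnorm(u_dc[occ] / tg$day_clinic_rate,
                                   lp$meanlog, lp$sdlog)), cap)
    }
    out$day_clinic_days <- dc

    eps <- zero
    if (tg$episodes_mean > 0) {
      u <- cop_u()
      v <- tg$episodes_sd^2
      if (v > tg$episodes_mean) {
        size <- tg$episodes_mean^2 / (v - tg$episodes_mean)
        eps <- qnbinom(u, size = size, mu = tg$episodes_mean)
      } else {
        eps <- qpois(u, tg$episodes_mean)
      }
    }
    out$episodes <- eps

    out$psychiatrist_visits <- if (tg$psychiatrist_visits_mean > 0)
      qpois(cop_u(), tg$psychiatrist_visits_mean) else zero

    emergency <- function(rate, cond_mean) {
      x <- zero
      if (rate > 0 && cond_mean > 0) {
        u <- cop_u()
        occ <- u < rate
        x[occ] <- q_ztp(u[occ] / rate, ztp_lambda(cond_mean))
      }
      x
    }
    out$emergency_service_contacts <-
      emergency(tg$emergency_service_rate, tg$emergency_service_mean)
    out$emergency_physician_contacts <-
      emergency(tg$emergency_physician_rate, tg$emergency_physician_mean)

    sick <- zero
    employed <- employment == "employed"
    cm <- conditional_moments(tg$sick_leave_mean, tg$sick_leave_sd,
                              tg$sick_leave_rate, "sick_leave_days")
    if (!is.null(cm) && any(employed)) {
      lp <- lnorm_match(cm$mean, cm$sd, cap)
      u <- cop_u()
      occ <- employed & (u < tg$sick_leave_rate)
      sick[occ] <- pmin(round(qlnorm(u[occ] / tg$sick_leave_rate,
                                     lp$meanlog, lp$sdlog)), cap)
    }
    out$sick_leave_days <- sick

    money <- function(mean, inpatient = FALSE) {
      if (mean == 0) return(zero)
      if (!inpatient) {
        u <- cop_u()
        lp <- lnorm_match(mean, tg$money_cv * mean)
        round_half_up(qlnorm(u, lp$meanlog, lp$sdlog), 2)
      } else {
        x <- zero
        rate <- tg$hospitalization_rate
        if (rate > 0 && any(occ_h)) {
          lp <- lnorm_match(mean / rate, tg$money_cv * mean / rate)
          u_c <- u_h[occ_h] / rate
          x[occ_h] <- round_half_up(qlnorm(u_c, lp$meanlog, lp$sdlog), 2)
        }
        x
      }
    }
    out$ebm_outpatient_eur <- money(tg$ebm_outpatient_mean)
    out$goa_outpatient_eur <- money(tg$goa_outpatient_mean)
    out$ebm_inpatient_eur <- money(tg$ebm_inpatient_mean, inpatient = TRUE)
    out$goa_inpatient_eur <- money(tg$goa_inpatient_mean, inpatient = TRUE)
    out$non_drug_eur <- money(tg$non_drug_mean)
    out$medication_eur <- money(tg$medication_mean)
    out$comorbid_medication_eur <- money(tg$comorbid_medication_mean)

    out$depot_injections <- if (tg$depot_injections_mean > 0)
      qbinom(cop_u(), 6, tg$depot_injections_mean / 6) else zero

    if (config$missingness > 0) {
      miss_fields <- c("episodes", "hospitalizations", "hospital_days",
                       "day_clinic_days", "psychiatrist_visits",
                       "emergency_service_contacts",
                       "emergency_physician_contacts", "sick_leave_days")
      for (f in miss_fields) {
        out[[f]][runif(n) < config$missingness] <- NA
      }
    }
    names(out) <- paste0(prefix, "_", names(out))
    out[paste0(prefix, "_", utilization_fields())]
  }

  a <- draw_phase(config$phase_a, "a")
  b <- draw_phase(config$phase_b, "b")
  dplyr::bind_cols(
    tibble(
      patient_id = sprintf("P%04d", seq_len(n)),
      age = age, sex = sex, employment = employment,
      insurance = insurance, copay_exempt = copay_exempt,
      age_at_diagnosis = age_dx
    ),
    as_tibble(a), as_tibble(b)
  )
}

#' Screen utilization against the observation window
#'
#' Splits a cohort into records consistent with the phase length and records
#' carrying contradictions — day counts reported for longer than the
#' observation period, or hospital days without any hospitalization. Nothing
#' is dropped silently: every rejected record carries the violated rule(s).
#'
#' @param records cohort tibble.
#' @param phase_length_days day cap per phase (default 183).
#' @return List with `retained` and `rejected` tibbles; `rejected` gains a
#'   `reason` column. `retained` and `rejected` partition the input.
#' @export
validate_utilization <- function(records, phase_length_days = 183) {
  if (phase_length_days <= 0) {
    abort("phase_length_days must be > 0", class = "switchbia_config_error")
  }
  day_fields <- c("hospital_days", "day_clinic_days", "sick_leave_days")
  reasons <- rep("", nrow(records))
  add <- function(reasons, bad, msg) {
    bad[is.na(bad)] <- FALSE
    ifelse(bad, paste0(reasons, ifelse(nzchar(reasons), "; ", ""), msg), reasons)
  }
  for (p in c("a", "b")) {
    for (f in day_fields) {
      col <- records[[paste0(p, "_", f)]]
      reasons <- add(reasons, col > phase_length_days,
                     sprintf("phase %s: %s exceeds observation period (> %d days)",
                             toupper(p), f, round(phase_length_days)))
    }
    bad <- records[[paste0(p, "_hospital_days")]] > 0 &
      records[[paste0(p, "_hospitalizations")]] == 0
    reasons <- add(reasons, bad,
                   sprintf("phase %s: hospital_days > 0 without hospitalization",
                           toupper(p)))
  }
  keep <- !nzchar(reasons)
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reasons[!keep]
  else rejected$reason <- character(0)
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}

#' Summarize one phase of a cohort
#'
#' Per-quantity mean, SD, analyzed n (non-missing) and event rate (share of
#' patients with >= 1 unit). Sick-leave days are summarized over the
#' employed stratum only, as in the study's endpoint definition.
#'
#' @param records cohort tibble (non-empty).
#' @param phase `"a"` or `"b"`.
#' @return Tibble: `quantity`, `mean`, `sd`, `n_analyzed`, `event_rate`.
#' @export
summarize_cohort <- function(records, phase = c("a", "b")) {
  phase <- match.arg(phase)
  if (nrow(records) == 0) abort("empty cohort",
                                class = "switchbia_value_error")
  rows <- lapply(utilization_fields(), function(f) {
    x <- records[[paste0(phase, "_", f)]]
    if (f == "sick_leave_days") x <- x[records$employment == "employed"]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(tibble(quantity = f, mean = NA_real_, sd = NA_real_,
                    n_analyzed = 0L, event_rate = NA_real_))
    }
    tibble(quantity = f, mean = mean(x), sd = sd(x),
           n_analyzed = length(x), event_rate = mean(x >= 1))
  })
  dplyr::bind_rows(rows)
}

#' Write / read a cohort table as delimited text
#'
#' Comma-separated, header row, one row per patient, missing values as
#' empty fields; round-trips exactly.
#'
#' @param records cohort tibble.
#' @param path CSV path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   tibble.
#' @name cohort_io
#' @export
write_cohort <- function(records, path) {
  readr::write_csv(records, path, na = "")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, na = "", show_col_types = FALSE,
                  col_types = readr::cols(
                    patient_id = readr::col_character(),
                    sex = readr::col_character(),
                    employment = readr::col_character(),
                    insurance = readr::col_character(),
                    copay_exempt = readr::col_logical()
                  ))
}
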