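test_that("identical config and seed give a byte-identical cohort", {
  cfg <- cohort_config(n = 40, seed = 11)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 40)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(c1, f1); write_cohort(c2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # different seed changes the draw
  expect_false(identical(c1, generate_cohort(cohort_config(n = 40, seed = 12))))
  # the caller's RNG stream is not consumed
  set.seed(99); x <- runif(1)
  set.seed(99); invisible(generate_cohort(cfg)); y <- runif(1)
  expect_identical(x, y)
})

test_that("structural invariants hold across seeds", {
  for (seed in c(3, 7, 21)) {
    coh <- generate_cohort(cohort_config(n = 80, seed = seed))
    util <- coh[, paste0(rep(c("a_", "b_"), each = 16),
                         rep(utilization_fields(), 2))]
    expect_true(all(as.matrix(util) >= 0))
    for (p in c("a", "b")) {
      expect_true(all(coh[[paste0(p, "_hospital_days")]] <= 183))
      expect_true(all(coh[[paste0(p, "_day_clinic_days")]] <= 183))
      expect_true(all(coh[[paste0(p, "_sick_leave_days")]] <= 183))
      expect_true(all(coh[[paste0(p, "_hospital_days")]] == 0 |
                        coh[[paste0(p, "_hospitalizations")]] >= 1))
      expect_true(all(coh[[paste0(p, "_sick_leave_days")]][
        coh$employment != "employed"] == 0))
    }
    expect_true(all(coh$age >= 18 & coh$age <= 65))
    expect_true(all(coh$age_at_diagnosis <= coh$age))
    expect_true(all(coh$employment %in%
                      c("employed", "unemployed", "retired", "education",
                        "unknown")))
  }
})

test_that("all-zero targets give an all-zero cohort", {
  zero_tg <- do.call(phase_targets, as.list(setNames(
    numeric(length(formals(phase_targets)) - 0),
    names(formals(phase_targets)))))
  cfg <- cohort_config(n = 25, seed = 5, phase_a = zero_tg, phase_b = zero_tg)
  coh <- generate_cohort(cfg)
  util <- coh[, paste0(rep(c("a_", "b_"), each = 16),
                       rep(utilization_fields(), 2))]
  expect_true(all(as.matrix(util) == 0))
  expect_equal(event_rate(coh, "a")$rate, 0)
})

test_that("default cohort reproduces the study's structure in expectation", {
  reps <- lapply(1:60, function(i) generate_cohort(cohort_config(seed = 100 + i)))
  employed <- sapply(reps, function(r) sum(r$employment == "employed"))
  expect_equal(mean(employed), 24, tolerance = 2 / 24)
  rate_a <- mean(sapply(reps, function(r) mean(r$a_hospitalizations >= 1)))
  expect_equal(rate_a, 0.551, tolerance = 0.02 / 0.551)
  days_a <- sapply(reps, function(r) mean(r$a_hospital_days))
  se <- sd(days_a) / sqrt(length(days_a))
  expect_lt(abs(mean(days_a) - 27.39), 3 * se)
  episodes_a <- mean(sapply(reps, function(r) mean(r$a_episodes)))
  expect_equal(episodes_a, 2.58, tolerance = 0.1 / 2.58)
})

test_that("invalid configuration is rejected naming the field", {
  expect_error(cohort_config(n = 0), "n")
  expect_error(cohort_config(frailty_correlation = 1.5), "frailty_correlation")
  expect_error(cohort_config(missingness = 1), "missingness")
  expect_error(cohort_config(employment = c(employed = 1)), "employment")
  tg <- default_phase_a()
  expect_error(phase_targets(
    hospitalization_rate = 1.2, hospitalization_mean = tg$hospitalization_mean,
    hospital_days_mean = tg$hospital_days_mean,
    hospital_days_sd = tg$hospital_days_sd,
    day_clinic_rate = tg$day_clinic_rate, day_clinic_mean = tg$day_clinic_mean,
    day_clinic_sd = tg$day_clinic_sd, episodes_mean = tg$episodes_mean,
    episodes_sd = tg$episodes_sd,
    psychiatrist_visits_mean = tg$psychiatrist_visits_mean,
    emergency_service_rate = tg$emergency_service_rate,
    emergency_service_mean = tg$emergency_service_mean,
    emergency_physician_rate = tg$emergency_physician_rate,
    emergency_physician_mean = tg$emergency_physician_mean,
    sick_leave_rate = tg$sick_leave_rate, sick_leave_mean = tg$sick_leave_mean,
    sick_leave_sd = tg$sick_leave_sd,
    ebm_outpatient_mean = tg$ebm_outpatient_mean,
    goa_outpatient_mean = tg$goa_outpatient_mean,
    ebm_inpatient_mean = tg$ebm_inpatient_mean,
    goa_inpatient_mean = tg$goa_inpatient_mean,
    non_drug_mean = tg$non_drug_mean, medication_mean = tg$medication_mean,
    comorbid_medication_mean = tg$comorbid_medication_mean
  ), "hospitalization_rate")
})

test_that("utilization screening partitions records and names the rule", {
  good <- lapply(1:7, function(i) make_record(a_hospital_days = i,
                                              a_hospitalizations = 1))
  bad <- list(
    make_record(a_hospital_days = 200, a_hospitalizations = 1),
    make_record(b_sick_leave_days = 190),
    make_record(a_day_clinic_days = 184)
  )
  coh <- do.call(make_cohort, c(good, bad))
  res <- validate_utilization(coh, phase_length_days = 183)
  expect_equal(nrow(res$retained), 7)
  expect_equal(nrow(res$rejected), 3)
  expect_match(res$rejected$reason[1], "hospital_days")
  expect_match(res$rejected$reason[2], "sick_leave_days")
  expect_match(res$rejected$reason[3], "day_clinic_days")
  expect_equal(nrow(res$retained) + nrow(res$rejected), nrow(coh))
  # all-zero record is retained; inconsistent coupling is rejected
  res0 <- validate_utilization(make_record())
  expect_equal(nrow(res0$retained), 1)
  resc <- validate_utilization(make_record(a_hospital_days = 5,
                                           a_hospitalizations = 0))
  expect_match(resc$rejected$reason, "without hospitalization")
  expect_error(validate_utilization(make_record(), phase_length_days = 0),
               "phase_length_days")
})

test_that("cohort summaries equal hand computation", {
  coh <- make_cohort(
    make_record(a_hospitalizations = 1, a_hospital_days = 10,
                a_sick_leave_days = 6),
    make_record(a_hospitalizations = 0),
    make_record(a_hospitalizations = 2, a_hospital_days = 30,
                employment = "unemployed"),
    make_record(a_episodes = 4, employment = "retired"),
    make_record(a_hospitalizations = 1, a_hospital_days = 2)
  )
  sm <- summarize_cohort(coh, "a")
  hosp <- sm[sm$quantity == "hospitalizations", ]
  expect_equal(hosp$mean, mean(c(1, 0, 2, 0, 1)))
  expect_equal(hosp$sd, sd(c(1, 0, 2, 0, 1)))
  expect_equal(hosp$event_rate, 3 / 5)
  expect_equal(hosp$n_analyzed, 5L)
  days <- sm[sm$quantity == "hospital_days", ]
  expect_equal(days$mean, mean(c(10, 0, 30, 0, 2)))
  # sick leave restricted to the employed stratum (3 of 5 records)
  sick <- sm[sm$quantity == "sick_leave_days", ]
  expect_equal(sick$n_analyzed, 3L)
  expect_equal(sick$mean, mean(c(6, 0, 0)))
  expect_error(summarize_cohort(coh[0, ], "a"), "empty")

  two <- make_cohort(make_record(a_hospitalizations = 1), make_record())
  expect_equal(summarize_cohort(two, "a")[
    summarize_cohort(two, "a")$quantity == "hospitalizations", ]$event_rate, 0.5)
})

test_that("item non-response shrinks analyzed denominators, not the cohort", {
  cfg <- cohort_config(n = 120, seed = 31, missingness = 0.25)
  coh <- generate_cohort(cfg)
  expect_equal(nrow(coh), 120)
  expect_true(anyNA(coh$a_hospitalizations))
  sm <- summarize_cohort(coh, "a")
  n_hosp <- sm$n_analyzed[sm$quantity == "hospitalizations"]
  expect_lt(n_hosp, 120)
  expect_equal(event_rate(coh, "a")$n_analyzed, n_hosp)
})

test_that("cohort tables round-trip through delimited text", {
  coh <- generate_cohort(cohort_config(n = 15, seed = 2, missingness = 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  expect_equal(as.data.frame(back), as.data.frame(coh))
})
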