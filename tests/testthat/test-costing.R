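test_that("patient-phase costing prices quantities at unit rates", {
  uc <- unit_cost_table()
  zero <- compute_patient_phase_cost(make_record(), "a", uc)
  expect_s3_class(zero, "cost_breakdown")
  expect_true(all(unclass(zero) == 0))
  expect_equal(breakdown_total(zero), 0)

  rec <- make_record(
    a_emergency_service_contacts = 2,
    a_emergency_physician_contacts = 1,
    a_hospital_days = 4, a_hospitalizations = 1,
    a_sick_leave_days = 10,
    a_ebm_outpatient_eur = 55.55, a_medication_eur = 120.10,
    b_depot_injections = 1
  )
  bd_a <- as_eur(unclass(compute_patient_phase_cost(rec, "a", uc)))
  expect_equal(bd_a[["emergency_services"]], 2 * 13.37)
  expect_equal(bd_a[["emergency_physician"]], 171)
  expect_equal(bd_a[["hospital_days"]], 4 * uc$hospital_day_eur)
  expect_equal(bd_a[["productivity_loss"]], 10 * 90)
  # pass-through euro fields are copied, not re-priced
  expect_equal(bd_a[["ebm_services"]], 55.55)
  expect_equal(bd_a[["medication"]], 120.10)
  bd_b <- as_eur(unclass(compute_patient_phase_cost(rec, "b", uc)))
  expect_equal(bd_b[["depot_injections"]], 515.97)
  expect_identical(attr(compute_patient_phase_cost(rec, "b", uc), "arm"), "depot")
})

test_that("sickness-benefit rule prices only days beyond the 42nd", {
  uc <- unit_cost_table()
  rec <- make_record(a_sick_leave_days = 50)
  all_days <- compute_patient_phase_cost(rec, "a", uc, "all_days")
  benefit <- compute_patient_phase_cost(rec, "a", uc, "sickness_benefit")
  expect_equal(as_eur(unclass(all_days))[["productivity_loss"]], 50 * 90)
  expect_equal(as_eur(unclass(benefit))[["productivity_loss"]], 8 * 90)
  short <- compute_patient_phase_cost(make_record(a_sick_leave_days = 30),
                                      "a", uc, "sickness_benefit")
  expect_equal(breakdown_total(short), 0)
  expect_error(compute_patient_phase_cost(rec, "a", uc, "half_days"),
               "productivity_rule")
})

test_that("aggregation matches hand-computed sums and per-case identity", {
  one <- cost_breakdown(eur_vec(medication = 100), "per_patient", "oral")
  agg1 <- aggregate_costs(list(one))
  expect_equal(ct_sample_total(agg1$component_table, "oral")[["medication"]], 100)
  expect_equal(ct_per_case(agg1$component_table, "oral")[["medication"]], 100)

  uc <- unit_cost_table()
  recs <- make_cohort(
    make_record(a_hospital_days = 2, a_hospitalizations = 1,
                a_medication_eur = 10.50),
    make_record(a_emergency_service_contacts = 3),
    make_record(a_sick_leave_days = 5)
  )
  bds <- lapply(1:3, function(i) compute_patient_phase_cost(recs[i, ], "a", uc))
  agg <- aggregate_costs(bds, n = 3)
  st <- ct_sample_total(agg$component_table, "oral")
  expect_equal(st[["hospital_days"]], 2 * uc$hospital_day_eur)
  expect_equal(st[["emergency_services"]], 3 * 13.37)
  expect_equal(st[["productivity_loss"]], 450)
  expect_equal(st[["medication"]], 10.50)
  expect_equal(ct_per_case(agg$component_table, "oral"), st / 3)
  expect_error(aggregate_costs(list()), "aggregate")
})

test_that("cost conservation is exact in cents and preserved by aggregation", {
  set.seed(42)
  for (i in 1:20) {
    eur <- setNames(round(runif(13, 0, 5000), 2), cost_categories())
    bd <- cost_breakdown(eur, "per_patient", "oral")
    expect_identical(sum(unclass(bd)), sum(as_cents(eur)))
    expect_equal(breakdown_total(bd), as_eur(sum(as_cents(eur))))
  }
  bds <- lapply(1:5, function(i) {
    cost_breakdown(setNames(round(runif(13, 0, 1000), 2), cost_categories()),
                   "per_patient", "depot")
  })
  agg <- aggregate_costs(bds, n = 5)
  st <- agg$component_table$totals$depot
  expect_identical(st, Reduce(`+`, lapply(bds, function(b) as.numeric(unclass(b)))))
  expect_true(all(st >= 0))
})

test_that("priced categories are linear in utilization", {
  uc <- unit_cost_table()
  rec <- make_record(a_hospital_days = 3, a_hospitalizations = 1,
                     a_day_clinic_days = 2, a_sick_leave_days = 4,
                     a_emergency_service_contacts = 1,
                     a_emergency_physician_contacts = 2)
  dbl <- make_record(a_hospital_days = 6, a_hospitalizations = 2,
                     a_day_clinic_days = 4, a_sick_leave_days = 8,
                     a_emergency_service_contacts = 2,
                     a_emergency_physician_contacts = 4)
  b1 <- unclass(compute_patient_phase_cost(rec, "a", uc))
  b2 <- unclass(compute_patient_phase_cost(dbl, "a", uc))
  expect_equal(as.numeric(b2), 2 * as.numeric(b1))
})

test_that("component-table loader validates categories and round-trips", {
  ct <- reference_component_table()
  expect_equal(ct$n, 132L)
  expect_equal(ct_per_case_total(ct, "oral"), 9935.38, tolerance = 0.05 / 9935)
  path <- withr::local_tempfile(fileext = ".csv")
  write_component_table(ct, path)
  ct2 <- load_component_table(path)
  expect_identical(ct$totals, ct2$totals)

  df <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(df[df$category != "hospital_days", ], path)
  expect_error(load_component_table(path), "hospital_days")
  df$category[1] <- "productivity"
  readr::write_csv(df, path)
  expect_error(load_component_table(path), "productivity")
})

test_that("direct/indirect split isolates productivity losses", {
  ct <- reference_component_table()
  oral <- split_direct_indirect(ct_breakdown(ct, "oral", "per_case"))
  depot <- split_direct_indirect(ct_breakdown(ct, "depot", "per_case"))
  expect_equal(oral[["direct"]], 9498.36, tolerance = 0.05 / 9498)
  expect_equal(depot[["direct"]], 4449.83, tolerance = 0.05 / 4449)
  expect_equal(oral[["direct"]] + oral[["indirect"]], oral[["total"]])
  zero <- split_direct_indirect(zero_breakdown())
  expect_equal(unname(zero), c(0, 0, 0))
})

test_that("medication share reproduces the oral-aripiprazole decomposition", {
  ct <- reference_component_table()
  bd <- ct_breakdown(ct, "oral", "per_case")
  expect_equal(medication_share(bd, "medication", 1562.49), 0.6383,
               tolerance = 1e-3)
  # the residual equals the published medication cost without oral aripiprazole
  med <- as_eur(unclass(bd)[["medication"]])
  expect_equal(med - 1562.49, 885.31, tolerance = 0.05)
  expect_equal(medication_share(bd, "medication", 0), 0)
  expect_error(medication_share(zero_breakdown(), "medication", 10), "0")
  expect_error(medication_share(bd, "medication", med + 1), "exceeds")
})

test_that("malformed breakdowns are rejected with the offending category", {
  eur <- eur_vec()
  expect_error(cost_breakdown(eur[-1], "per_patient"), "productivity_loss")
  expect_error(cost_breakdown(c(eur, bogus = 1)), "bogus")
  eur["medication"] <- -5
  expect_error(cost_breakdown(eur), ">= 0")
  expect_error(unit_cost_table(hospital_day_eur = 500), "range")
})
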