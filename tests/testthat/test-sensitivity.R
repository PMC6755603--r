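ct_ref <- reference_component_table()
params_ref <- reference_sensitivity_parameters()

test_that("mean +/- sd bounds truncate at zero", {
  expect_equal(truncated_bounds(27.39, 41.37),
               c(min_value = 0, max_value = 68.76))
  expect_equal(truncated_bounds(40.06, 29.62),
               c(min_value = 10.44, max_value = 69.68))
  expect_equal(truncated_bounds(5, 0), c(min_value = 5, max_value = 5))
  expect_error(truncated_bounds(5, -1), "sd")
})

test_that("varying a parameter to its base value recovers the base case", {
  ident <- sensitivity_parameter(
    "identity", "probability", "hospital_days",
    arms = list(oral = list(base_mean = 27.39, sd = 0),
                depot = list(base_mean = 5.56, sd = 0))
  )
  for (arm in c("oral", "depot")) {
    for (dir in c("min", "max")) {
      r <- vary_parameter(ct_ref, ident, dir, arm)
      expect_equal(r$per_case_eur, ct_per_case_total(ct_ref, arm),
                   tolerance = 1e-12)
    }
  }
})

test_that("ratio scaling touches exactly one category", {
  base_pc <- ct_per_case(ct_ref, "oral")
  p <- params_ref[["productivity_loss_days"]]
  r <- vary_parameter(ct_ref, p, "max", "oral")
  # total moved exactly by the change in the linked component
  expect_equal(r$per_case_eur - sum(base_pc),
               r$component_eur - base_pc[["productivity_loss"]])
  expect_equal(r$component_eur,
               base_pc[["productivity_loss"]] * 69.68 / 40.06)
  expect_equal(r$sample_total_eur, r$per_case_eur * 132)
})

test_that("per-case total is monotone in the varied occurrence value", {
  for (nm in c("productivity_loss_days", "day_clinic_days",
               "hospital_days_occurrence")) {
    p <- params_ref[[nm]]
    for (arm in c("oral", "depot")) {
      lo <- vary_parameter(ct_ref, p, "min", arm)$per_case_eur
      hi <- vary_parameter(ct_ref, p, "max", arm)$per_case_eur
      base <- ct_per_case_total(ct_ref, arm)
      expect_lte(lo, base + 1e-9)
      expect_gte(hi, base - 1e-9)
    }
  }
})

test_that("a min bound truncated to zero removes the whole component", {
  # depot hospital days: 5.56 - 20.70 truncates to 0
  r <- vary_parameter(ct_ref, params_ref[["hospital_days_occurrence"]],
                      "min", "depot")
  base <- ct_per_case(ct_ref, "depot")
  expect_equal(r$per_case_eur, sum(base) - base[["hospital_days"]])
  expect_equal(r$component_eur, 0)
})

test_that("cost-mode parameters rescale by the unit-price ratio", {
  # day-clinic: explicit base rate 240, range 240-720
  p <- params_ref[["day_clinic_cost"]]
  base <- ct_per_case(ct_ref, "oral")
  r_min <- vary_parameter(ct_ref, p, "min", "oral")
  r_max <- vary_parameter(ct_ref, p, "max", "oral")
  expect_equal(r_min$component_eur, base[["day_clinic_pia"]])
  expect_equal(r_max$component_eur, base[["day_clinic_pia"]] * 720 / 240)
  # hospital day: implied base rate = component / mean days
  ph <- params_ref[["hospital_day_cost"]]
  implied <- base[["hospital_days"]] / 27.39
  r <- vary_parameter(ct_ref, ph, "max", "oral")
  expect_equal(r$component_eur, base[["hospital_days"]] * 385 / implied)
  # the catalogue preset uses the 120-360 range instead
  cat_p <- reference_sensitivity_parameters("catalogue")[["day_clinic_cost"]]
  expect_equal(c(cat_p$min_cost, cat_p$max_cost), c(120, 360))
})

test_that("one-way analysis enumerates base case and all variations", {
  res <- one_way_analysis(ct_ref, params_ref, default_scenarios())
  expect_equal(nrow(res), 2 + 7 * 2 * 2)
  expect_equal(res$parameter[1:2], c("base_case", "base_case"))
  expect_equal(sum(grepl("^pop_eur", names(res))), 2)
  # population figures are per-case times the scenario count, full precision
  pop <- res[[grep("^pop_eur", names(res))[1]]]
  expect_equal(pop, res$per_case_eur * 656000)
  # no scenarios: per-case and sample columns only
  res0 <- one_way_analysis(ct_ref, params_ref, list())
  expect_false(any(grepl("^pop_eur", names(res0))))
  dup <- c(params_ref, params_ref[1])
  expect_error(one_way_analysis(ct_ref, dup, list()), "duplicate")
})

test_that("parameters rank hospital days first and emergency contacts last", {
  res <- one_way_analysis(ct_ref, params_ref, list())
  for (arm in c("oral", "depot")) {
    rk <- rank_parameters(res, arm)
    expect_equal(rk$parameter[1], "hospital_days_occurrence")
    expect_setequal(utils::tail(rk$parameter, 2),
                    c("emergency_physician_contacts",
                      "emergency_service_contacts"))
    expect_true(all(diff(rk$range_eur) <= 0))
  }
  single <- one_way_analysis(ct_ref, params_ref["hospital_days_occurrence"],
                             list())
  expect_equal(rank_parameters(single, "oral")$parameter,
               "hospital_days_occurrence")
  missing_dir <- res[res$direction != "min", ]
  expect_error(rank_parameters(missing_dir, "oral"), "missing direction")
})

test_that("invalid sensitivity definitions are rejected", {
  expect_error(sensitivity_parameter(
    "bad", "probability", "hospital_days",
    arms = list(oral = list(base_mean = 5, sd = 0, min_value = 6,
                            max_value = 7),
                depot = list(base_mean = 5, sd = 0))), "bounds")
  expect_error(sensitivity_parameter(
    "bad2", "cost", "hospital_days",
    arms = list(oral = list(base_mean = 5, sd = 0),
                depot = list(base_mean = 5, sd = 0))), "min_cost")
  zero_ct <- component_table(eur_vec(), eur_vec(), n = 2)
  p <- params_ref[["hospital_days_occurrence"]]
  expect_error(vary_parameter(
    zero_ct, sensitivity_parameter(
      "z", "probability", "hospital_days",
      arms = list(oral = list(base_mean = 0, sd = 0, min_value = 0,
                              max_value = 3),
                  depot = list(base_mean = 0, sd = 0))),
    "max", "oral"), "base mean")
})
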