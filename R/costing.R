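#' The thirteen cost categories of the budget-impact model
#'
#' Per-patient, per-phase costs are decomposed into exactly these categories,
#' mirroring the resource-utilization items reimbursed by the German
#' statutory health insurance: productivity losses (sick-leave days, the only
#' indirect category), outpatient physician services under the statutory
#' (EBM) and private (GOÄ) fee schedules, day-clinic / psychiatric institute
#' ambulance (PIA) days, EBM/GOÄ services during hospitalization, hospital
#' days, emergency services and emergency-physician contacts, non-drug
#' interventions, depot injections, antipsychotic medication, and medication
#' for pre-existing (comorbid) conditions.
#'
#' @return Character vector of the 13 category keys, in table order.
#' @export
cost_categories <- function() {
  c("productivity_loss", "ebm_services", "goa_services", "day_clinic_pia",
    "ebm_inpatient", "goa_inpatient", "hospital_days", "emergency_services",
    "emergency_physician", "non_drug_interventions", "depot_injections",
    "medication", "comorbid_medication")
}

#' Unit-cost table
#'
#' Base reimbursement rates per resource unit. Day-clinic and hospital days
#' have admissible price ranges rather than a single national rate; their
#' base defaults to the range midpoint and both are overridable. All other
#' categories are either fixed national rates or pass-through euro amounts
#' already priced at source (EBM/GOÄ sums, medication, non-drug
#' interventions).
#'
#' @param sick_leave_day_eur euros per sick-leave day (default 90).
#' @param day_clinic_day_eur euros per day-clinic/PIA day; default midpoint
#'   of `day_clinic_range_eur`.
#' @param day_clinic_range_eur admissible range, default `c(120, 360)`.
#' @param hospital_day_eur euros per hospital day; default midpoint of
#'   `hospital_day_range_eur`.
#' @param hospital_day_range_eur admissible range, default `c(90, 385)`.
#' @param emergency_service_eur euros per emergency-service contact (13.37).
#' @param emergency_physician_eur euros per emergency-physician contact (171).
#' @param depot_injection_eur euros per aripiprazole-depot injection (515.97).
#' @return An object of class `unit_cost_table` (a named list).
#' @examples
#' uc <- unit_cost_table()
#' uc$emergency_service_eur
#' @export
unit_cost_table <- function(sick_leave_day_eur = 90,
                            day_clinic_day_eur = NULL,
                            day_clinic_range_eur = c(120, 360),
                            hospital_day_eur = NULL,
                            hospital_day_range_eur = c(90, 385),
                            emergency_service_eur = 13.37,
                            emergency_physician_eur = 171,
                            depot_injection_eur = 515.97) {
  day_clinic_day_eur <- day_clinic_day_eur %||% mean(day_clinic_range_eur)
  hospital_day_eur <- hospital_day_eur %||% mean(hospital_day_range_eur)
  uc <- list(
    sick_leave_day_eur = sick_leave_day_eur,
    day_clinic_day_eur = day_clinic_day_eur,
    day_clinic_range_eur = day_clinic_range_eur,
    hospital_day_eur = hospital_day_eur,
    hospital_day_range_eur = hospital_day_range_eur,
    emergency_service_eur = emergency_service_eur,
    emergency_physician_eur = emergency_physician_eur,
    depot_injection_eur = depot_injection_eur
  )
  rates <- unlist(uc[grepl("_eur$", names(uc))])
  if (any(rates < 0)) {
    abort("all unit costs must be >= 0", class = "switchbia_config_error")
  }
  check_range <- function(base, rng, what) {
    if (length(rng) != 2 || rng[1] > rng[2]) {
      abort(paste0(what, " range must be c(lower, upper)"),
            class = "switchbia_config_error")
    }
    if (base < rng[1] || base > rng[2]) {
      abort(paste0(what, " base rate must lie inside its admissible range"),
            class = "switchbia_config_error")
    }
  }
  check_range(uc$day_clinic_day_eur, uc$day_clinic_range_eur, "day-clinic")
  check_range(uc$hospital_day_eur, uc$hospital_day_range_eur, "hospital-day")
  structure(uc, class = "unit_cost_table")
}

new_cost_breakdown <- function(cents, scope, arm = NA_character_) {
  stopifnot(setequal(names(cents), cost_categories()))
  structure(cents[cost_categories()], scope = scope, arm = arm,
            class = "cost_breakdown")
}

#' Construct a cost breakdown
#'
#' A `cost_breakdown` is a named vector over the 13 [cost_categories()],
#' held as integer cents with a `scope` (`per_patient`, `per_case`,
#' `sample_total` or `population_total`) and treatment `arm` attribute.
#'
#' @param eur named numeric vector of euro amounts; every category must be
#'   present (missing categories are not defaulted, so that malformed tables
#'   are caught early).
#' @param scope one of `"per_patient"`, `"per_case"`, `"sample_total"`,
#'   `"population_total"`.
#' @param arm `"oral"`, `"depot"` or `NA`.
#' @return A `cost_breakdown` object.
#' @seealso [breakdown_total()], [split_direct_indirect()]
#' @export
cost_breakdown <- function(eur,
                           scope = c("per_patient", "per_case",
                                     "sample_total", "population_total"),
                           arm = NA_character_) {
  scope <- match.arg(scope)
  missing <- setdiff(cost_categories(), names(eur))
  extra <- setdiff(names(eur), cost_categories())
  if (length(missing) || length(extra)) {
    abort(paste0(
      "cost breakdown categories do not match the 13 model categories",
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", "))
    ), class = "switchbia_category_error")
  }
  if (any(eur < 0)) {
    abort("cost breakdown values must be >= 0", class = "switchbia_value_error")
  }
  new_cost_breakdown(as_cents(eur), scope, arm)
}

#' Zero breakdown (all categories 0)
#' @inheritParams cost_breakdown
#' @export
zero_breakdown <- function(scope = "per_patient", arm = NA_character_) {
  cost_breakdown(setNames(numeric(13), cost_categories()), scope, arm)
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("<cost_breakdown scope=%s arm=%s>\n",
              attr(x, "scope"), attr(x, "arm")))
  df <- data.frame(category = names(x), eur = format_eur(as_eur(unclass(x))))
  print(df, row.names = FALSE, right = FALSE)
  cat(sprintf("total: %s\n", format_eur(as_eur(sum(x)))))
  invisible(x)
}

#' @export
as_tibble.cost_breakdown <- function(x, ...) {
  tibble(category = names(x), eur = as_eur(as.numeric(unclass(x))))
}

#' Total of a cost breakdown, in euros
#' @param breakdown a [cost_breakdown()].
#' @return Numeric scalar, euros (exact cent sum / 100).
#' @export
breakdown_total <- function(breakdown) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  as_eur(sum(unclass(breakdown)))
}

#' Cost one patient-phase
#'
#' Turns the utilization block of a patient record into euros per category:
#' day and contact quantities are multiplied by their unit rates; the
#' EBM/GOÄ, medication and non-drug fields are already euro amounts at
#' source and pass through unchanged. The productivity rule maps raw
#' sick-leave days to cost-relevant days: `"all_days"` prices every day,
#' `"sickness_benefit"` only days beyond the 42nd per phase (sickness
#' benefit replaces employer-paid sick pay from the sixth week of continuous
#' sick leave, which is when productivity losses hit the statutory health
#' insurance).
#'
#' @param record a single patient record: one row of a cohort table (see
#'   [generate_cohort()]), or any list with the `a_*`/`b_*` utilization
#'   fields.
#' @param phase `"a"` (oral antipsychotics) or `"b"` (aripiprazole-depot).
#' @param unit_costs a [unit_cost_table()].
#' @param productivity_rule `"all_days"` or `"sickness_benefit"`.
#' @return A `cost_breakdown` with scope `per_patient` and the arm implied
#'   by the phase.
#' @examples
#' rec <- as.list(setNames(numeric(32), paste0(
#'   rep(c("a_", "b_"), each = 16), rep(utilization_fields(), 2))))
#' rec$a_emergency_service_contacts <- 2
#' compute_patient_phase_cost(rec, "a", unit_cost_table())["emergency_services"]
#' @export
compute_patient_phase_cost <- function(record, phase = c("a", "b"),
                                       unit_costs = unit_cost_table(),
                                       productivity_rule = c("all_days", "sickness_benefit")) {
  phase <- match.arg(phase)
  if (is.character(productivity_rule) &&
      !all(productivity_rule %in% c("all_days", "sickness_benefit"))) {
    abort(paste0("unknown productivity_rule: ", productivity_rule[1]),
          class = "switchbia_config_error")
  }
  productivity_rule <- match.arg(productivity_rule)
  record <- as.list(record)
  g <- function(field) {
    v <- record[[paste0(phase, "_", field)]]
    if (is.null(v) || is.na(v)) 0 else as.numeric(v)
  }
  sick_days <- g("sick_leave_days")
  relevant_days <- switch(productivity_rule,
    all_days = sick_days,
    sickness_benefit = max(sick_days - 42, 0)
  )
  eur <- c(
    productivity_loss = relevant_days * unit_costs$sick_leave_day_eur,
    ebm_services = g("ebm_outpatient_eur"),
    goa_services = g("goa_outpatient_eur"),
    day_clinic_pia = g("day_clinic_days") * unit_costs$day_clinic_day_eur,
    ebm_inpatient = g("ebm_inpatient_eur"),
    goa_inpatient = g("goa_inpatient_eur"),
    hospital_days = g("hospital_days") * unit_costs$hospital_day_eur,
    emergency_services = g("emergency_service_contacts") * unit_costs$emergency_service_eur,
    emergency_physician = g("emergency_physician_contacts") * unit_costs$emergency_physician_eur,
    non_drug_interventions = g("non_drug_eur"),
    depot_injections = g("depot_injections") * unit_costs$depot_injection_eur,
    medication = g("medication_eur"),
    comorbid_medication = g("comorbid_medication_eur")
  )
  cost_breakdown(eur, scope = "per_patient",
                 arm = if (phase == "a") "oral" else "depot")
}

#' Aggregate per-patient breakdowns to per-case means and sample totals
#'
#' @param breakdowns list of `per_patient` [cost_breakdown()] objects (one
#'   arm, or mixed arms — aggregation is per arm).
#' @param n cohort size used as the per-case denominator; defaults to the
#'   number of breakdowns per arm.
#' @return A list with `component_table` (see [component_table()]) and
#'   `sample_totals`, a named list of `sample_total` breakdowns per arm.
#'   Per-case values satisfy per_case = sample_total / n at full precision.
#' @export
aggregate_costs <- function(breakdowns, n = NULL) {
  if (length(breakdowns) == 0) {
    abort("no breakdowns to aggregate", class = "switchbia_value_error")
  }
  stopifnot(all(vapply(breakdowns, inherits, logical(1), "cost_breakdown")))
  arms <- vapply(breakdowns, attr, character(1), "arm")
  arms[is.na(arms)] <- "oral"
  totals <- list()
  for (arm in c("oral", "depot")) {
    sub <- breakdowns[arms == arm]
    cents <- if (length(sub)) {
      Reduce(`+`, lapply(sub, function(b) as.numeric(unclass(b))))
    } else {
      numeric(13)
    }
    totals[[arm]] <- new_cost_breakdown(
      setNames(cents, cost_categories()), "sample_total", arm)
  }
  n <- n %||% max(table(factor(arms, c("oral", "depot"))))
  if (n < 1) abort("n must be >= 1", class = "switchbia_value_error")
  ct <- new_component_table(
    oral_cents = as.numeric(unclass(totals$oral)),
    depot_cents = as.numeric(unclass(totals$depot)),
    n = n
  )
  list(component_table = ct, sample_totals = totals)
}

#' Cost a whole synthetic cohort into a component table
#'
#' Convenience wrapper: costs every patient in both phases (phase A priced
#' as the oral arm, phase B as the depot arm) and aggregates.
#'
#' @param records cohort tibble from [generate_cohort()].
#' @inheritParams compute_patient_phase_cost
#' @return A [component_table()] with `n = nrow(records)`.
#' @export
cohort_component_table <- function(records, unit_costs = unit_cost_table(),
                                   productivity_rule = "all_days") {
  if (nrow(records) == 0) abort("empty cohort", class = "switchbia_value_error")
  bds <- c(
    lapply(seq_len(nrow(records)), function(i)
      compute_patient_phase_cost(records[i, ], "a", unit_costs, productivity_rule)),
    lapply(seq_len(nrow(records)), function(i)
      compute_patient_phase_cost(records[i, ], "b", unit_costs, productivity_rule))
  )
  aggregate_costs(bds, n = nrow(records))$component_table
}

#' Split a breakdown into direct, indirect and total costs
#'
#' Indirect costs are the productivity losses (sick-leave days); everything
#' else — medication, hospital days, physician services, etc. — is a direct
#' cost. The identity direct + indirect = total holds exactly in cents.
#'
#' @param breakdown a [cost_breakdown()] or a [component_table()] arm via
#'   [ct_breakdown()].
#' @return Named numeric vector `c(direct, indirect, total)`, euros.
#' @examples
#' split_direct_indirect(ct_breakdown(reference_component_table(), "oral"))
#' @export
split_direct_indirect <- function(breakdown) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  cents <- unclass(breakdown)
  indirect <- cents[["productivity_loss"]]
  total <- sum(cents)
  c(direct = as_eur(total - indirect), indirect = as_eur(indirect),
    total = as_eur(total))
}

#' Share of a sub-component within one cost category
#'
#' Used for the decomposition of oral medication costs into the part caused
#' by oral aripiprazole itself and the rest.
#'
#' @param breakdown a [cost_breakdown()].
#' @param category one of [cost_categories()].
#' @param sub_component_eur euro amount of the sub-component; must not
#'   exceed the category value.
#' @return Proportion in `[0, 1]`.
#' @examples
#' ct <- reference_component_table()
#' medication_share(ct_breakdown(ct, "oral", "per_case"), "medication", 1562.49)
#' @export
medication_share <- function(breakdown, category = "medication",
                             sub_component_eur) {
  stopifnot(inherits(breakdown, "cost_breakdown"))
  category <- match.arg(category, cost_categories())
  value <- as_eur(unclass(breakdown)[[category]])
  if (value == 0) {
    if (sub_component_eur == 0) return(0)
    abort("category value is 0 but sub-component is not",
          class = "switchbia_value_error")
  }
  if (sub_component_eur > value + 1e-9) {
    abort("sub-component exceeds the category value",
          class = "switchbia_value_error")
  }
  sub_component_eur / value
}
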