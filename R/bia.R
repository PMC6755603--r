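#' Population scenario for prevalence-based extrapolation
#'
#' Germany counts roughly 82 million inhabitants in the 18–65 bracket used
#' for the prevalence estimate; a 12-month schizophrenia prevalence between
#' 0.8% and 0.9% yields 656,000–738,000 prevalent patients. The market share
#' is the fraction of those patients assumed to receive the treatment under
#' evaluation (1.0 reproduces the full-substitution scenario, which is
#' explicitly labelled as hypothetical in reports).
#'
#' @param prevalence proportion in (0, 1).
#' @param base_population persons (default 82,000,000).
#' @param market_share proportion in \[0, 1\] (default 1).
#' @param label scenario label; autogenerated when `NULL`.
#' @return A `population_scenario` object; `$patients` holds
#'   `round(base_population * prevalence) * market_share`, kept fractional
#'   (scenario cells are exact products, not rounded head counts).
#' @examples
#' population_scenario(0.008)$patients
#' @export
population_scenario <- function(prevalence, base_population = 82e6,
                                market_share = 1, label = NULL) {
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    abort("prevalence must be in (0, 1)", class = "switchbia_config_error")
  }
  if (market_share < 0 || market_share > 1) {
    abort("market_share must be in [0, 1]", class = "switchbia_config_error")
  }
  if (base_population <= 0) {
    abort("base_population must be > 0", class = "switchbia_config_error")
  }
  label <- label %||% sprintf("prevalence %.2f%%, share %.0f%%",
                              100 * prevalence, 100 * market_share)
  structure(
    list(base_population = base_population, prevalence = prevalence,
         market_share = market_share,
         patients = round(base_population * prevalence) * market_share,
         label = label),
    class = "population_scenario"
  )
}

#' @export
print.population_scenario <- function(x, ...) {
  cat(sprintf("<population_scenario> %s: %s patients\n", x$label,
              format(x$patients, big.mark = ",")))
  invisible(x)
}

#' Extrapolate one arm's cost to a population scenario
#'
#' Linear prevalence-based extrapolation: unrounded per-case cost
#' (sample total / n) times the scenario patient count.
#'
#' @param ct a [component_table()].
#' @param arm `"oral"` or `"depot"`.
#' @param scenario a [population_scenario()].
#' @return Euros (numeric scalar, full precision).
#' @examples
#' extrapolate_total_cost(reference_component_table(), "oral",
#'                        population_scenario(0.008))
#' @export
extrapolate_total_cost <- function(ct, arm = c("oral", "depot"), scenario) {
  arm <- match.arg(arm)
  stopifnot(inherits(ct, "component_table"),
            inherits(scenario, "population_scenario"))
  if (ct$n == 0) abort("component table has n = 0",
                       class = "switchbia_value_error")
  ct_per_case_total(ct, arm) * scenario$patients
}

#' Budget impact (savings) of the switch under one scenario
#'
#' @inheritParams extrapolate_total_cost
#' @return One-row tibble: scenario label, patient count, `cost_oral_eur`,
#'   `cost_depot_eur`, `savings_eur` (= oral − depot) and
#'   `per_case_savings_eur` (= oral per-case − depot per-case).
#' @examples
#' compute_savings(reference_component_table(), population_scenario(0.008))
#' @export
compute_savings <- function(ct, scenario) {
  oral <- extrapolate_total_cost(ct, "oral", scenario)
  depot <- extrapolate_total_cost(ct, "depot", scenario)
  label <- scenario$label
  patients <- scenario$patients
  tibble(
    scenario = label,
    patients = patients,
    cost_oral_eur = oral,
    cost_depot_eur = depot,
    savings_eur = oral - depot,
    per_case_savings_eur = ct_per_case_total(ct, "oral") -
      ct_per_case_total(ct, "depot")
  )
}

#' Market-share scenario grid
#'
#' Crosses each substitution share with each prevalence scenario and
#' reports both arms' extrapolated costs and the budget impact. Shares of
#' 4–12% reflect observed depot uptake; 100% is the hypothetical
#' full-substitution bound.
#'
#' @param ct a [component_table()].
#' @param shares numeric vector of market shares in \[0, 1\].
#' @param scenarios list of [population_scenario()] (their own
#'   `market_share` is replaced by each element of `shares`).
#' @return Tibble with one row per share × scenario: label, share,
#'   patients, `cost_oral_eur`, `cost_depot_eur`, `savings_eur`.
#' @examples
#' market_share_scenarios(reference_component_table(), c(0.04, 0.12),
#'                        list(population_scenario(0.008)))
#' @export
market_share_scenarios <- function(ct, shares, scenarios) {
  if (length(shares) == 0) abort("shares must be non-empty",
                                 class = "switchbia_config_error")
  if (any(shares < 0 | shares > 1)) {
    abort("market shares must be in [0, 1]", class = "switchbia_config_error")
  }
  if (length(scenarios) == 0) abort("scenarios must be non-empty",
                                    class = "switchbia_config_error")
  rows <- list()
  for (sc in scenarios) {
    for (sh in shares) {
      sc_sh <- population_scenario(sc$prevalence, sc$base_population,
                                   market_share = sh)
      rows[[length(rows) + 1L]] <- tibble(
        scenario = sc$label,
        prevalence = sc$prevalence,
        market_share = sh,
        patients = sc_sh$patients,
        cost_oral_eur = extrapolate_total_cost(ct, "oral", sc_sh),
        cost_depot_eur = extrapolate_total_cost(ct, "depot", sc_sh),
        savings_eur = NA_real_
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$savings_eur <- out$cost_oral_eur - out$cost_depot_eur
  dplyr::arrange(out, .data$prevalence, .data$market_share)
}

#' Default prevalence scenarios (0.8% and 0.9% of 82 million)
#' @return List of two [population_scenario()] objects (656,000 and
#'   738,000 prevalent patients).
#' @export
default_scenarios <- function() {
  list(population_scenario(0.008), population_scenario(0.009))
}
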