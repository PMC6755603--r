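#' Mean ± SD bounds truncated at zero
#'
#' Occurrence-type parameters are varied by one standard deviation around
#' their mean; a lower bound below zero is truncated to zero (days and
#' contact counts cannot be negative).
#'
#' @param mean,sd numeric scalars, `sd >= 0`.
#' @return Named numeric `c(min_value, max_value)`.
#' @examples
#' truncated_bounds(27.39, 41.37)
#' @export
truncated_bounds <- function(mean, sd) {
  if (sd < 0) abort("sd must be >= 0", class = "switchbia_config_error")
  c(min_value = max(mean - sd, 0), max_value = mean + sd)
}

#' Define one sensitivity parameter
#'
#' A parameter of the one-way analysis, in one of two modes:
#' * `probability`: an occurrence quantity (days or contacts) whose per-arm
#'   mean is varied between explicit bounds (usually mean ± SD truncated at
#'   zero, see [truncated_bounds()]); the linked cost component is rescaled
#'   by `varied / base_mean`.
#' * `cost`: a unit price varied over its admissible range; the component is
#'   rescaled by `varied_cost / base_unit_cost`. When `base_unit_cost` is
#'   `NA`, the rate implied by the table is used
#'   (per-case component / base mean quantity of that arm).
#'
#' @param name unique parameter name.
#' @param mode `"probability"` or `"cost"`.
#' @param category linked [cost_categories()] key.
#' @param arms named list (`oral`, `depot`) of lists with `base_mean`, `sd`,
#'   `min_value`, `max_value`; when `min_value`/`max_value` are omitted they
#'   default to [truncated_bounds()] of mean and SD.
#' @param min_cost,max_cost,base_unit_cost euros; cost mode only.
#' @return A `sensitivity_parameter` object.
#' @export
sensitivity_parameter <- function(name, mode = c("probability", "cost"),
                                  category, arms,
                                  min_cost = NA_real_, max_cost = NA_real_,
                                  base_unit_cost = NA_real_) {
  mode <- match.arg(mode)
  category <- match.arg(category, cost_categories())
  arms <- lapply(arms, function(a) {
    a <- as.list(a)
    a[vapply(a, function(v) length(v) != 1 || is.na(v), logical(1))] <- NULL
    if (is.null(a$min_value) || is.null(a$max_value)) {
      tb <- truncated_bounds(a$base_mean, a$sd %||% 0)
      a$min_value <- a$min_value %||% unname(tb["min_value"])
      a$max_value <- a$max_value %||% unname(tb["max_value"])
    }
    if (a$min_value < 0) abort("min_value must be >= 0",
                               class = "switchbia_config_error")
    if (a$min_value > a$base_mean + 1e-9 || a$base_mean > a$max_value + 1e-9) {
      abort(paste0(name, ": bounds must satisfy min <= base mean <= max"),
            class = "switchbia_config_error")
    }
    a
  })
  if (mode == "cost" && (is.na(min_cost) || is.na(max_cost))) {
    abort("cost mode requires min_cost and max_cost",
          class = "switchbia_config_error")
  }
  structure(
    list(name = name, mode = mode, category = category, arms = arms,
         min_cost = min_cost, max_cost = max_cost,
         base_unit_cost = base_unit_cost),
    class = "sensitivity_parameter"
  )
}

varied_factor <- function(ct, param, direction, arm) {
  a <- param$arms[[arm]]
  if (param$mode == "probability") {
    varied <- if (direction == "min") a$min_value else a$max_value
    if (a$base_mean == 0) {
      if (varied == 0) return(list(factor = 0, varied = 0))
      abort(paste0(param$name, ": base mean is 0, cannot rescale"),
            class = "switchbia_value_error")
    }
    list(factor = varied / a$base_mean, varied = varied)
  } else {
    varied <- if (direction == "min") param$min_cost else param$max_cost
    base_cost <- param$base_unit_cost
    if (is.na(base_cost)) {
      if (a$base_mean == 0) {
        abort(paste0(param$name, ": no base unit cost and base mean is 0"),
              class = "switchbia_value_error")
      }
      base_cost <- ct_per_case(ct, arm)[[param$category]] / a$base_mean
    }
    list(factor = varied / base_cost, varied = varied)
  }
}

#' Vary one parameter, one direction, one arm
#'
#' Rescales the linked cost component of the chosen arm while keeping all
#' other components at base values (single-touch), and recomputes per-case
#' and sample totals at full precision.
#'
#' @param ct a [component_table()].
#' @param param a [sensitivity_parameter()].
#' @param direction `"min"` or `"max"`.
#' @param arm `"oral"` or `"depot"`.
#' @return One-row tibble: parameter, mode, direction, arm, category,
#'   varied value, `component_eur`, `per_case_eur`, `sample_total_eur`.
#' @examples
#' params <- reference_sensitivity_parameters()
#' vary_parameter(reference_component_table(),
#'                params[["hospital_days_occurrence"]], "max", "oral")
#' @export
vary_parameter <- function(ct, param, direction = c("min", "max"),
                           arm = c("oral", "depot")) {
  direction <- match.arg(direction)
  arm <- match.arg(arm)
  stopifnot(inherits(ct, "component_table"),
            inherits(param, "sensitivity_parameter"))
  vf <- varied_factor(ct, param, direction, arm)
  per_case <- ct_per_case(ct, arm)
  base_component <- per_case[[param$category]]
  new_component <- base_component * vf$factor
  per_case_total <- sum(per_case) - base_component + new_component
  tibble(
    parameter = param$name, mode = param$mode, direction = direction,
    arm = arm, category = param$category, varied_value = vf$varied,
    component_eur = new_component,
    per_case_eur = per_case_total,
    sample_total_eur = per_case_total * ct$n
  )
}

#' One-way (univariate) deterministic sensitivity analysis
#'
#' Varies each parameter to its lower and upper bound, one at a time and
#' per arm, rebuilding per-case and sample totals and extrapolating each
#' result through every population scenario. The base case is included as
#' the reference row.
#'
#' @param ct a [component_table()].
#' @param params list of [sensitivity_parameter()] (unique names).
#' @param scenarios list of [population_scenario()]; may be empty, in which
#'   case only per-case and sample columns are produced.
#' @return Tibble: base-case row first, then one row per
#'   parameter × direction × arm, with one `pop_eur.<label>` column per
#'   scenario.
#' @examples
#' res <- one_way_analysis(reference_component_table(),
#'                         reference_sensitivity_parameters(),
#'                         default_scenarios())
#' @export
one_way_analysis <- function(ct, params, scenarios = default_scenarios()) {
  if (length(params) == 0) abort("params must be non-empty",
                                 class = "switchbia_config_error")
  nms <- vapply(params, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    abort(paste0("duplicate parameter names: ",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
          class = "switchbia_config_error")
  }
  base_rows <- lapply(c("oral", "depot"), function(arm) {
    tibble(parameter = "base_case", mode = NA_character_, direction = "base",
           arm = arm, category = NA_character_, varied_value = NA_real_,
           component_eur = NA_real_,
           per_case_eur = ct_per_case_total(ct, arm),
           sample_total_eur = ct_per_case_total(ct, arm) * ct$n)
  })
  var_rows <- list()
  for (p in params) {
    for (arm in c("oral", "depot")) {
      for (dir in c("min", "max")) {
        var_rows[[length(var_rows) + 1L]] <- vary_parameter(ct, p, dir, arm)
      }
    }
  }
  out <- dplyr::bind_rows(c(base_rows, var_rows))
  for (sc in scenarios) {
    out[[paste0("pop_eur.", sc$label)]] <- out$per_case_eur * sc$patients
  }
  out
}

#' Rank parameters by induced per-case cost range
#'
#' Tornado-style ordering: for each parameter the range is the spread of the
#' per-case total between its min and max rows in one arm; parameters are
#' returned in descending range order.
#'
#' @param results tibble from [one_way_analysis()] (or rows of
#'   [vary_parameter()] covering both directions).
#' @param arm `"oral"` or `"depot"`.
#' @return Tibble `parameter`, `min_per_case_eur`, `max_per_case_eur`,
#'   `range_eur`, sorted descending by range.
#' @export
rank_parameters <- function(results, arm = c("oral", "depot")) {
  arm <- match.arg(arm)
  res <- dplyr::filter(results, .data$arm == !!arm,
                       .data$parameter != "base_case")
  counts <- table(res$parameter)
  if (any(counts < 2)) {
    abort(paste0("missing direction for: ",
                 paste(names(counts)[counts < 2], collapse = ", ")),
          class = "switchbia_value_error")
  }
  out <- res |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      min_per_case_eur = min(.data$per_case_eur),
      max_per_case_eur = max(.data$per_case_eur),
      range_eur = max(.data$per_case_eur) - min(.data$per_case_eur),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$range_eur))
  out
}

#' The study's seven sensitivity parameters
#'
#' Five occurrence parameters (sick-leave days, day-clinic/PIA days,
#' hospital days, emergency-physician contacts, emergency-service contacts)
#' varied between their listed per-arm bounds, plus two unit-cost parameters
#' (day-clinic day price, hospital-day price) varied over their price
#' ranges. Two conflicting day-clinic price ranges circulate (catalogue
#' per-diems 120–360 €; the analysis preset 240–720 €); both are shipped as
#' named presets.
#'
#' @param day_clinic_preset `"analysis"` (240–720 €) or `"catalogue"`
#'   (120–360 €).
#' @return Named list of [sensitivity_parameter()] objects.
#' @export
reference_sensitivity_parameters <- function(day_clinic_preset = c("analysis", "catalogue")) {
  day_clinic_preset <- match.arg(day_clinic_preset)
  path <- system.file("extdata", "sensitivity_parameters.csv",
                      package = "switchbia", mustWork = TRUE)
  params <- load_sensitivity_parameters(path)
  if (day_clinic_preset == "catalogue") {
    p <- params[["day_clinic_cost"]]
    p$min_cost <- 120; p$max_cost <- 360; p$base_unit_cost <- 240
    params[["day_clinic_cost"]] <- p
  }
  params
}

#' Load a sensitivity-parameter registry from delimited text
#'
#' Long format, one row per parameter × arm, columns: `name`, `mode`,
#' `category`, `arm`, `base_mean`, `sd`, `min_value`, `max_value`,
#' `base_unit_cost`, `min_cost`, `max_cost` (cost columns may be empty for
#' probability mode).
#'
#' @param path CSV path.
#' @return Named list of [sensitivity_parameter()] objects, file order.
#' @export
load_sensitivity_parameters <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  params <- list()
  for (nm in unique(df$name)) {
    sub <- df[df$name == nm, ]
    arms <- lapply(stats::setNames(c("oral", "depot"), c("oral", "depot")),
                   function(a) {
      row <- sub[sub$arm == a, ]
      if (nrow(row) == 0) row <- sub[1, ]   # arm-independent parameter
      list(base_mean = row$base_mean, sd = row$sd,
           min_value = row$min_value, max_value = row$max_value)
    })
    params[[nm]] <- sensitivity_parameter(
      name = nm, mode = sub$mode[1], category = sub$category[1], arms = arms,
      min_cost = sub$min_cost[1], max_cost = sub$max_cost[1],
      base_unit_cost = sub$base_unit_cost[1]
    )
  }
  params
}

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param results tibble from [one_way_analysis()].
#' @param arm `"oral"` or `"depot"`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_tornado <- function(results, arm = c("oral", "depot")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    abort("plot_tornado requires ggplot2")
  }
  arm <- match.arg(arm)
  base <- results$per_case_eur[results$parameter == "base_case" &
                                 results$arm == arm][1]
  rk <- rank_parameters(results, arm)
  rk$parameter <- factor(rk$parameter, levels = rev(rk$parameter))
  ggplot2::ggplot(rk, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$min_per_case_eur,
                                       xend = .data$max_per_case_eur,
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "per-case cost (EUR)", y = NULL,
                  title = paste("One-way sensitivity,", arm, "arm"))
}
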