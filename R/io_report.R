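#' Load and validate a run configuration
#'
#' Structured-text (YAML, which includes JSON) configuration driving a full
#' analysis run. Exactly one costing entry mode must be active:
#' `component_table` (reproducing a published per-case table) or `cohort`
#' (patient-level costing of a synthetic or supplied cohort). All schema
#' violations are collected and reported together.
#'
#' Recognised keys: `seed`, `locale` (`default`/`german`),
#' `productivity_rule`, `component_table: {path}` or `cohort: {file}` /
#' `cohort: {n, seed, frailty_correlation, missingness}` (generator
#' overrides), `unit_costs` (overrides for [unit_cost_table()] arguments),
#' `scenarios` (list of `{prevalence, base_population, market_share,
#' label}`), `market_shares` (numeric vector), `sensitivity`
#' (`default`, `none`, or a registry CSV path), `reference_rate`,
#' `output_dir`.
#'
#' @param path configuration file path.
#' @return A validated `run_config` list with defaults filled in; the raw
#'   file's md5 hash is attached as attribute `config_hash`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "switchbia_config_error")
  }
  # keep literal y/n/yes/no keys (e.g. the cohort size `n`) as strings
  # rather than YAML 1.1 booleans, except genuine true/false
  keep <- function(x) {
    if (tolower(x) %in% c("true", "false")) as.logical(x) else x
  }
  raw <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                               "bool#no" = keep))
  if (is.null(raw) || !is.list(raw) || length(raw) == 0) {
    abort("config file is empty or not a mapping",
          class = "switchbia_config_error")
  }
  problems <- character(0)
  has_ct <- !is.null(raw$component_table)
  has_cohort <- !is.null(raw$cohort)
  if (has_ct && has_cohort) {
    problems <- c(problems,
                  "component_table and cohort are mutually exclusive; configure exactly one")
  }
  if (!has_ct && !has_cohort) {
    problems <- c(problems,
                  "one of component_table or cohort must be configured")
  }
  cfg <- list(
    seed = raw$seed %||% 20160501,
    locale = raw$locale %||% "default",
    productivity_rule = raw$productivity_rule %||% "all_days",
    mode = if (has_ct) "component_table" else "cohort",
    component_table = raw$component_table,
    cohort = raw$cohort,
    unit_costs = raw$unit_costs %||% list(),
    scenarios = raw$scenarios %||%
      list(list(prevalence = 0.008), list(prevalence = 0.009)),
    market_shares = as.numeric(raw$market_shares %||% c(0.04, 0.12)),
    sensitivity = raw$sensitivity %||% "default",
    reference_rate = raw$reference_rate %||% 0.381,
    output_dir = raw$output_dir %||% "."
  )
  if (!cfg$locale %in% c("default", "german")) {
    problems <- c(problems, "locale must be 'default' or 'german'")
  }
  if (!cfg$productivity_rule %in% c("all_days", "sickness_benefit")) {
    problems <- c(problems,
                  "productivity_rule must be 'all_days' or 'sickness_benefit'")
  }
  for (sc in cfg$scenarios) {
    pv <- sc$prevalence
    if (is.null(pv) || !is.numeric(pv) || pv <= 0 || pv >= 1) {
      problems <- c(problems, "every scenario needs prevalence in (0, 1)")
    }
  }
  if (any(cfg$market_shares < 0 | cfg$market_shares > 1)) {
    problems <- c(problems, "market_shares must lie in [0, 1]")
  }
  if (length(problems)) {
    abort(paste0("invalid run config:\n- ",
                 paste(problems, collapse = "\n- ")),
          class = "switchbia_config_error")
  }
  attr(cfg, "config_hash") <- unname(tools::md5sum(path))
  class(cfg) <- "run_config"
  cfg
}

#' The packaged default run configuration
#'
#' Component-table mode on the study's reference table, prevalence
#' scenarios 0.8%/0.9%, market shares 4% and 12%, default sensitivity
#' registry.
#'
#' @return Path to the packaged YAML file.
#' @export
default_run_config <- function() {
  system.file("extdata", "default_config.yaml", package = "switchbia",
              mustWork = TRUE)
}

resolve_component_table <- function(cfg) {
  if (cfg$mode == "component_table") {
    path <- cfg$component_table$path
    if (is.null(path)) reference_component_table()
    else load_component_table(path)
  } else {
    uc <- do.call(unit_cost_table, cfg$unit_costs)
    records <- if (!is.null(cfg$cohort$file)) {
      read_cohort(cfg$cohort$file)
    } else {
      gen_args <- cfg$cohort[names(cfg$cohort) %in%
                              c("n", "seed", "frailty_correlation",
                                "missingness", "phase_length_days")]
      gen_args$seed <- gen_args$seed %||% cfg$seed
      generate_cohort(do.call(cohort_config, gen_args))
    }
    records <- validate_utilization(records)$retained
    attr(records, "switchbia_cohort") <- TRUE
    ct <- cohort_component_table(records, uc, cfg$productivity_rule)
    list(ct = ct, records = records)
  }
}

#' Run the full budget-impact pipeline
#'
#' Resolves the costing input (component table or cohort), computes
#' per-case and sample costs, savings, population extrapolations,
#' market-share scenarios and the one-way sensitivity analysis, plus — in
#' cohort mode — the endpoint statistics.
#'
#' @param config a `run_config` from [load_run_config()], or a path.
#' @return A results bundle (list) consumable by [render_report()].
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  src <- resolve_component_table(config)
  records <- NULL
  if (is.list(src) && !inherits(src, "component_table")) {
    records <- src$records
    ct <- src$ct
  } else {
    ct <- src
  }
  scenarios <- lapply(config$scenarios, function(sc) {
    population_scenario(sc$prevalence,
                        base_population = sc$base_population %||% 82e6,
                        market_share = sc$market_share %||% 1,
                        label = sc$label)
  })
  savings <- dplyr::bind_rows(lapply(scenarios, function(sc)
    compute_savings(ct, sc)))
  market <- market_share_scenarios(ct, config$market_shares, scenarios)
  sens <- NULL
  if (!identical(config$sensitivity, "none")) {
    params <- if (identical(config$sensitivity, "default")) {
      reference_sensitivity_parameters()
    } else {
      load_sensitivity_parameters(config$sensitivity)
    }
    sens <- one_way_analysis(ct, params, scenarios)
  }
  endpoints <- if (!is.null(records)) {
    endpoint_table(records, config$reference_rate)
  }
  bundle <- list(
    component_table = ct,
    per_case = tibble(
      category = ct$totals$category,
      oral_eur = ct_per_case(ct, "oral"),
      depot_eur = ct_per_case(ct, "depot")
    ),
    sample_totals = tibble(
      category = ct$totals$category,
      oral_eur = ct_sample_total(ct, "oral"),
      depot_eur = ct_sample_total(ct, "depot")
    ),
    direct_indirect = list(
      oral = split_direct_indirect(ct_breakdown(ct, "oral")),
      depot = split_direct_indirect(ct_breakdown(ct, "depot"))
    ),
    savings = savings,
    market_share = market,
    sensitivity = sens,
    endpoints = endpoints,
    records = records,
    seed = config$seed,
    config_hash = attr(config, "config_hash") %||% NA_character_,
    locale = config$locale
  )
  class(bundle) <- "switchbia_bundle"
  bundle
}

fmt_table <- function(df, locale) {
  for (nm in names(df)) {
    if (grepl("_eur$", nm) && is.numeric(df[[nm]])) {
      df[[nm]] <- format_eur(df[[nm]], locale)
    }
    if (grepl("^pop_eur", nm) && is.numeric(df[[nm]])) {
      df[[nm]] <- format_eur(df[[nm]], locale)
    }
  }
  df
}

write_report_table <- function(df, path, locale, seed, hash) {
  body <- readr::format_csv(fmt_table(df, locale))
  writeLines(c(sprintf("# seed=%s config_hash=%s locale=%s",
                       seed, hash, locale),
               sub("\n$", "", body)), path)
  invisible(path)
}

#' Read back a rendered report table
#'
#' Parses the locale-formatted euro columns back to numerics; together with
#' [render_report()] this round-trips values to the cent.
#'
#' @param path CSV written by [render_report()].
#' @param locale the locale it was written with.
#' @return Tibble with numeric euro columns.
#' @export
read_report_table <- function(path, locale = c("default", "german")) {
  locale <- match.arg(locale)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  for (nm in names(df)) {
    if (grepl("_eur$|^pop_eur", nm)) df[[nm]] <- parse_eur(df[[nm]], locale)
    else {
      num <- suppressWarnings(as.numeric(df[[nm]]))
      if (!anyNA(num) || all(is.na(df[[nm]]) == is.na(num))) df[[nm]] <- num
    }
  }
  df
}

#' Render the report tables of a pipeline run
#'
#' Writes delimited-text tables mirroring the published layout — per-case
#' costs, sample totals, population totals, market-share grid, and (when
#' computed) sensitivity results and endpoint statistics — plus a
#' human-readable summary. Every file embeds the seed and config hash in a
#' leading comment line. The German locale renders
#' `260.704.250,62`-style numbers; the default locale `260,704,250.62`.
#'
#' @param bundle result of [run_pipeline()].
#' @param output_dir directory (created if needed).
#' @param locale `"default"` or `"german"`; defaults to the bundle's.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(bundle, output_dir, locale = NULL) {
  if (!inherits(bundle, "switchbia_bundle") || is.null(bundle$per_case)) {
    abort("empty results bundle", class = "switchbia_value_error")
  }
  locale <- locale %||% bundle$locale %||% "default"
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- bundle$seed; hash <- bundle$config_hash
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    write_report_table(df, p, locale, seed, hash)
    files <<- c(files, p)
  }
  emit(bundle$per_case, "table_per_case.csv")
  emit(bundle$sample_totals, "table_sample_totals.csv")
  pop <- dplyr::select(bundle$savings, "scenario", "patients",
                       "cost_oral_eur", "cost_depot_eur", "savings_eur")
  emit(pop, "table_population.csv")
  emit(bundle$market_share, "table_market_share.csv")
  if (!is.null(bundle$sensitivity)) emit(bundle$sensitivity, "table_sensitivity.csv")
  if (!is.null(bundle$endpoints)) {
    emit(bundle$endpoints, "table_endpoints.csv")
  }
  ct <- bundle$component_table
  sm <- c(
    sprintf("# seed=%s config_hash=%s locale=%s", seed, hash, locale),
    "Budget impact of switching oral antipsychotics to aripiprazole-depot",
    sprintf("cohort size n = %d", ct$n),
    sprintf("per-case cost, oral arm:  %s", format_eur(ct_per_case_total(ct, "oral"), locale, symbol = TRUE)),
    sprintf("per-case cost, depot arm: %s", format_eur(ct_per_case_total(ct, "depot"), locale, symbol = TRUE)),
    sprintf("per-case savings:         %s", format_eur(
      ct_per_case_total(ct, "oral") - ct_per_case_total(ct, "depot"),
      locale, symbol = TRUE)),
    "note: scenarios with market share 1.0 assume 100% substitution, a hypothetical upper bound",
    vapply(seq_len(nrow(bundle$savings)), function(i) {
      sprintf("%s: oral %s, depot %s, savings %s",
              bundle$savings$scenario[i],
              format_eur(bundle$savings$cost_oral_eur[i], locale, TRUE),
              format_eur(bundle$savings$cost_depot_eur[i], locale, TRUE),
              format_eur(bundle$savings$savings_eur[i], locale, TRUE))
    }, character(1))
  )
  p <- file.path(output_dir, "summary.txt")
  writeLines(sm, p)
  files <- c(files, p)
  invisible(files)
}
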