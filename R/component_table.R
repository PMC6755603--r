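new_component_table <- function(oral_cents, depot_cents, n) {
  structure(
    list(
      totals = tibble(
        category = cost_categories(),
        oral = as.numeric(oral_cents),
        depot = as.numeric(depot_cents)
      ),
      n = as.integer(n)
    ),
    class = "component_table"
  )
}

#' Per-case component table for the two treatment arms
#'
#' The central costing container: mean cost per patient over one 6-month
#' phase ("per case"), by category, for the oral-antipsychotic arm and the
#' aripiprazole-depot arm, together with the cohort size `n`. Internally the
#' object stores exact sample totals in integer cents; per-case values are
#' derived as `sample_total / n` at full precision, which is also the value
#' used for population extrapolation (the printed per-case table is a
#' rounded view of it).
#'
#' @param oral_eur,depot_eur named numeric vectors over [cost_categories()],
#'   euros, at the scope given by `scope`.
#' @param n cohort size (per-case denominator).
#' @param scope whether the supplied values are `"sample_total"` euros or
#'   `"per_case"` euros (in which case sample totals are n × per-case).
#' @return A `component_table` object.
#' @seealso [reference_component_table()], [load_component_table()],
#'   [ct_per_case()], [ct_breakdown()]
#' @export
component_table <- function(oral_eur, depot_eur, n,
                            scope = c("sample_total", "per_case")) {
  scope <- match.arg(scope)
  check <- function(x, arm) {
    missing <- setdiff(cost_categories(), names(x))
    extra <- setdiff(names(x), cost_categories())
    if (length(missing) || length(extra)) {
      abort(paste0(
        "component table (", arm, " arm) categories invalid",
        if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
        if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", "))
      ), class = "switchbia_category_error")
    }
    if (any(x < 0)) abort("component values must be >= 0",
                          class = "switchbia_value_error")
    x[cost_categories()]
  }
  oral_eur <- check(oral_eur, "oral")
  depot_eur <- check(depot_eur, "depot")
  if (n < 1) abort("n must be >= 1", class = "switchbia_value_error")
  if (scope == "per_case") {
    oral_eur <- oral_eur * n
    depot_eur <- depot_eur * n
  }
  new_component_table(as_cents(oral_eur), as_cents(depot_eur), n)
}

#' @export
print.component_table <- function(x, ...) {
  cat(sprintf("<component_table n=%d> per-case euros:\n", x$n))
  df <- data.frame(
    category = x$totals$category,
    oral = format_eur(x$totals$oral / 100 / x$n),
    depot = format_eur(x$totals$depot / 100 / x$n)
  )
  print(df, row.names = FALSE, right = FALSE)
  cat(sprintf("per-case total: oral %s, depot %s\n",
              format_eur(ct_per_case_total(x, "oral")),
              format_eur(ct_per_case_total(x, "depot"))))
  invisible(x)
}

#' Component-table accessors
#'
#' `ct_per_case()` returns unrounded per-case euros per category;
#' `ct_per_case_total()` the unrounded per-case total; `ct_sample_total()`
#' exact sample-total euros; `ct_breakdown()` a [cost_breakdown()] view of
#' one arm at per-case (rounded to cents for presentation) or sample-total
#' scope.
#'
#' @param ct a [component_table()].
#' @param arm `"oral"` or `"depot"`.
#' @param scope `"per_case"` or `"sample_total"` (for `ct_breakdown()`).
#' @return Named numerics (euros), or a `cost_breakdown`.
#' @name component_table_accessors
#' @export
ct_per_case <- function(ct, arm = c("oral", "depot")) {
  arm <- match.arg(arm)
  setNames(ct$totals[[arm]] / 100 / ct$n, ct$totals$category)
}

#' @rdname component_table_accessors
#' @export
ct_per_case_total <- function(ct, arm = c("oral", "depot")) {
  arm <- match.arg(arm)
  sum(ct$totals[[arm]]) / 100 / ct$n
}

#' @rdname component_table_accessors
#' @export
ct_sample_total <- function(ct, arm = c("oral", "depot")) {
  arm <- match.arg(arm)
  setNames(ct$totals[[arm]] / 100, ct$totals$category)
}

#' @rdname component_table_accessors
#' @export
ct_breakdown <- function(ct, arm = c("oral", "depot"),
                         scope = c("sample_total", "per_case")) {
  arm <- match.arg(arm)
  scope <- match.arg(scope)
  cents <- if (scope == "sample_total") {
    ct$totals[[arm]]
  } else {
    round_half_up(ct$totals[[arm]] / ct$n, 0)
  }
  new_cost_breakdown(setNames(cents, ct$totals$category), scope, arm)
}

#' The study's reference component table
#'
#' The per-case cost table of the German switch study (n = 132; exact
#' sample totals in euros, from which the published per-case values follow
#' by division), shipped as a plain-text fixture under `inst/extdata` and
#' loadable without any other configuration. Oral-arm per-case total
#' 9935.38 €, depot 4557.56 €.
#'
#' @return A [component_table()] with n = 132.
#' @examples
#' ct <- reference_component_table()
#' round(ct_per_case_total(ct, "oral"), 2)
#' @export
reference_component_table <- function() {
  path <- system.file("extdata", "component_table_sample_totals.csv",
                      package = "switchbia", mustWork = TRUE)
  load_component_table(path)
}

#' Load a component table from delimited text
#'
#' The file must have columns `category`, `oral_eur`, `depot_eur` and `n`
#' (cohort size, constant across rows), one row per cost category; exactly
#' the 13 model categories must be present. `scope` in the file is
#' `sample_total` euros.
#'
#' @param path CSV file path.
#' @return A [component_table()].
#' @seealso [write_component_table()] for the inverse.
#' @export
load_component_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  need <- c("category", "oral_eur", "depot_eur", "n")
  if (!all(need %in% names(df))) {
    abort(paste0("component table file must have columns: ",
                 paste(need, collapse = ", ")),
          class = "switchbia_config_error")
  }
  if (length(unique(df$n)) != 1) {
    abort("column n must be constant", class = "switchbia_config_error")
  }
  component_table(
    oral_eur = setNames(df$oral_eur, df$category),
    depot_eur = setNames(df$depot_eur, df$category),
    n = df$n[1],
    scope = "sample_total"
  )
}

#' Write a component table as delimited text
#'
#' Inverse of [load_component_table()]; round-trips values to the cent.
#'
#' @param ct a [component_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_component_table <- function(ct, path) {
  df <- tibble(
    category = ct$totals$category,
    oral_eur = ct$totals$oral / 100,
    depot_eur = ct$totals$depot / 100,
    n = ct$n
  )
  readr::write_csv(df, path)
  invisible(path)
}
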