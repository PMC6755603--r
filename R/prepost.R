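#' Event rate of a utilization quantity
#'
#' Proportion of patients with at least one unit of `quantity` in the given
#' phase; records with a missing value are excluded from the denominator
#' (item non-response).
#'
#' @param records cohort tibble.
#' @param phase `"a"` or `"b"`.
#' @param quantity a [utilization_fields()] name (default
#'   `"hospitalizations"`, the primary endpoint).
#' @return List with `rate` and `n_analyzed`.
#' @examples
#' coh <- generate_cohort(cohort_config(n = 50, seed = 1))
#' event_rate(coh, "a")$rate
#' @export
event_rate <- function(records, phase = c("a", "b"),
                       quantity = "hospitalizations") {
  phase <- match.arg(phase)
  if (nrow(records) == 0) abort("empty cohort",
                                class = "switchbia_value_error")
  quantity <- match.arg(quantity, utilization_fields())
  x <- records[[paste0(phase, "_", quantity)]]
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    abort(paste0("all values of ", quantity, " are missing"),
          class = "switchbia_value_error")
  }
  list(rate = mean(x >= 1), n_analyzed = length(x))
}

#' Paired pre-post comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test of phase A against phase B, each
#' patient serving as their own control. Zero differences are dropped
#' before ranking (the classical convention); the exact signed-rank
#' distribution is used for up to 25 effective pairs without ties among the
#' absolute differences, otherwise the normal approximation with continuity
#' correction. A Lilliefors-corrected Kolmogorov-Smirnov normality p-value
#' of the paired differences is attached as advisory metadata — the
#' reported test is always the Wilcoxon.
#'
#' @param values_a,values_b equal-length numeric vectors (pairs with any
#'   `NA` are dropped).
#' @param endpoint label for the result row.
#' @return One-row tibble of class `endpoint_result`: endpoint, phase
#'   means, `n_analyzed`, `statistic` (V), `p_value`, `method`,
#'   `normality_p`, `degenerate`. When every pair is tied the result is
#'   flagged degenerate and carries no p-value.
#' @examples
#' compare_paired(c(3, 5, 2, 7, 1, 4), c(1, 2, 2, 3, 0, 1))
#' @export
compare_paired <- function(values_a, values_b, endpoint = "endpoint") {
  if (length(values_a) != length(values_b)) {
    abort("values_a and values_b must have equal length",
          class = "switchbia_value_error")
  }
  ok <- !is.na(values_a) & !is.na(values_b)
  a <- values_a[ok]; b <- values_b[ok]
  if (length(a) == 0) abort("no complete pairs",
                            class = "switchbia_value_error")
  d <- a - b
  normality_p <- if (length(unique(d)) >= 5 && sd(d) > 0) {
    tryCatch(nortest::lillie.test(d)$p.value, error = function(e) NA_real_)
  } else NA_real_
  d_nz <- d[d != 0]
  if (length(d_nz) == 0) {
    return(tibble(
      endpoint = endpoint, mean_a = mean(a), mean_b = mean(b),
      n_analyzed = length(a), n_effective = 0L,
      statistic = NA_real_, p_value = NA_real_, method = "degenerate",
      normality_p = normality_p, degenerate = TRUE
    ))
  }
  exact <- length(d_nz) <= 25 && !anyDuplicated(abs(d_nz))
  # one-sample signed-rank on the nonzero differences: equivalent to the
  # paired test, but lets the exact distribution be used after zeros are
  # dropped (wilcox.test would otherwise fall back to the approximation)
  wt <- suppressWarnings(
    wilcox.test(d_nz, exact = exact, correct = TRUE)
  )
  tibble(
    endpoint = endpoint, mean_a = mean(a), mean_b = mean(b),
    n_analyzed = length(a), n_effective = length(d_nz),
    statistic = unname(wt$statistic), p_value = wt$p.value,
    method = if (exact) "wilcoxon signed-rank (exact)"
             else "wilcoxon signed-rank (normal approx., cc)",
    normality_p = normality_p, degenerate = FALSE
  )
}

#' Endpoint table for a cohort
#'
#' Runs the paired comparison for the study's endpoints (hospitalizations,
#' hospital days, episodes, day-clinic days, psychiatrist visits, and
#' sick-leave days on the employed stratum only) plus the one-sided
#' binomial test of the phase-B hospitalization rate against an external
#' reference rate.
#'
#' @param records cohort tibble.
#' @param reference_rate external hospitalization rate to test the depot
#'   phase against (default 0.381).
#' @return Tibble of endpoint rows; attribute `binomial` holds the
#'   reference-rate test result.
#' @export
endpoint_table <- function(records, reference_rate = 0.381) {
  pick <- function(f, employed_only = FALSE) {
    idx <- if (employed_only) records$employment == "employed" else TRUE
    list(a = records[[paste0("a_", f)]][idx],
         b = records[[paste0("b_", f)]][idx])
  }
  specs <- list(
    hospitalizations = FALSE, hospital_days = FALSE, episodes = FALSE,
    day_clinic_days = FALSE, psychiatrist_visits = FALSE,
    sick_leave_days = TRUE
  )
  rows <- lapply(names(specs), function(f) {
    v <- pick(f, specs[[f]])
    compare_paired(v$a, v$b, endpoint = f)
  })
  out <- dplyr::bind_rows(rows)
  er <- event_rate(records, "b", "hospitalizations")
  x <- records$b_hospitalizations
  x <- x[!is.na(x)]
  attr(out, "binomial") <- list(
    successes = sum(x >= 1), n = length(x), reference_rate = reference_rate,
    p_value = binomial_vs_reference(sum(x >= 1), length(x), reference_rate,
                                    side = "less"),
    rate = er$rate
  )
  out
}

#' One-sided exact binomial test against a reference rate
#'
#' Exact binomial tail probability of observing a hospitalization count at
#' least as extreme as `successes` out of `n` under the external reference
#' rate (default the published 38.1% oral-antipsychotic rate).
#'
#' @param successes number of patients with the event.
#' @param n number analyzed.
#' @param reference_rate null proportion, in (0, 1).
#' @param side `"less"` (is the observed rate lower?) or `"greater"`.
#' @return The exact tail p-value.
#' @examples
#' binomial_vs_reference(0, 10, 0.381, "less")  # (1 - 0.381)^10
#' @export
binomial_vs_reference <- function(successes, n, reference_rate = 0.381,
                                  side = c("less", "greater")) {
  side <- match.arg(side)
  if (reference_rate <= 0 || reference_rate >= 1) {
    abort("reference_rate must be in (0, 1)",
          class = "switchbia_config_error")
  }
  if (successes < 0 || successes > n) {
    abort("successes must be between 0 and n",
          class = "switchbia_value_error")
  }
  if (side == "less") pbinom(successes, n, reference_rate)
  else pbinom(successes - 1, n, reference_rate, lower.tail = FALSE)
}

exact_binomial_power <- function(n, p0, p1, alpha) {
  # lower-tail rejection region: largest c with P(X <= c | p0) <= alpha
  c_crit <- qbinom(alpha, n, p0) # qbinom gives smallest q with F(q) >= alpha
  while (c_crit >= 0 && pbinom(c_crit, n, p0) > alpha) c_crit <- c_crit - 1
  if (c_crit < 0) return(0)
  pbinom(c_crit, n, p1)
}

#' Required sample size against a reference hospitalization rate
#'
#' Smallest n giving the target power to show that the true rate `p1 = p0 -
#' detectable_difference` falls below the reference rate `p0`, by a
#' one-sided test at level `alpha`. Two methods: `"exact"` (exact binomial
#' rejection region; power is sawtoothed in n, the first n reaching the
#' target is returned) and `"normal"` (one-sample normal approximation).
#'
#' @param reference_rate null proportion p0 (default 0.381).
#' @param detectable_difference absolute rate difference to detect
#'   (default 0.11).
#' @param power target power (default 0.80), must be < 1.
#' @param alpha one-sided significance level (default 0.05).
#' @param method `"normal"` or `"exact"`.
#' @return List: `n`, `method`, `p0`, `p1`, `power`, `alpha`.
#' @examples
#' required_sample_size()$n
#' @export
required_sample_size <- function(reference_rate = 0.381,
                                 detectable_difference = 0.11,
                                 power = 0.80, alpha = 0.05,
                                 method = c("normal", "exact")) {
  method <- match.arg(method)
  if (power >= 1 || power <= 0) abort("power must be in (0, 1)",
                                      class = "switchbia_config_error")
  if (alpha <= 0 || alpha >= 1) abort("alpha must be in (0, 1)",
                                      class = "switchbia_config_error")
  p0 <- reference_rate
  p1 <- p0 - detectable_difference
  if (p1 <= 0 || p1 >= 1 || p0 <= 0 || p0 >= 1) {
    abort("rates must lie in (0, 1)", class = "switchbia_config_error")
  }
  n <- if (method == "normal") {
    za <- qnorm(1 - alpha); zb <- qnorm(power)
    ceiling(((za * sqrt(p0 * (1 - p0)) + zb * sqrt(p1 * (1 - p1))) /
               (p0 - p1))^2)
  } else {
    nn <- 1
    while (exact_binomial_power(nn, p0, p1, alpha) < power && nn < 1e6) {
      nn <- nn + 1
    }
    nn
  }
  list(n = as.integer(n), method = method, p0 = p0, p1 = p1,
       power = power, alpha = alpha)
}

#' Inflate a sample size for expected dropout
#'
#' @param n required analyzable sample size.
#' @param dropout_rate expected dropout proportion in \[0, 1).
#' @return `ceiling(n / (1 - dropout_rate))`.
#' @examples
#' inflate_for_dropout(116, 0.10)  # 129
#' @export
inflate_for_dropout <- function(n, dropout_rate) {
  if (dropout_rate < 0 || dropout_rate >= 1) {
    abort("dropout_rate must be in [0, 1)",
          class = "switchbia_config_error")
  }
  as.integer(ceiling(n / (1 - dropout_rate)))
}
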