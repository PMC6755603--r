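# A flat patient record with all utilization at zero, overridable by name,
# e.g. make_record(a_hospital_days = 10, a_hospitalizations = 1).
make_record <- function(..., employment = "employed") {
  flat <- setNames(
    as.list(numeric(32)),
    paste0(rep(c("a_", "b_"), each = 16), rep(utilization_fields(), 2))
  )
  rec <- c(
    list(patient_id = "P0001", age = 40, sex = "female",
         employment = employment, insurance = "statutory",
         copay_exempt = FALSE, age_at_diagnosis = 30),
    flat
  )
  over <- list(...)
  rec[names(over)] <- over
  tibble::as_tibble(rec)
}

make_cohort <- function(...) {
  dplyr::bind_rows(...)
}

# brute-force null distribution of the signed-rank statistic: enumerate all
# 2^n sign assignments of the ranked absolute differences
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# euro vector over all 13 categories, zero except the named ones
eur_vec <- function(...) {
  x <- setNames(numeric(13), cost_categories())
  over <- c(...)
  x[names(over)] <- over
  x
}
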