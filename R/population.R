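# National incidence projection and the discounted effective population
# that scales per-patient value of information to the population level.

#' Linear incidence projection of heart failure patients
#'
#' Yearly incident-patient counts `base + increment * t` for
#' `t = 0 .. years - 1`. The defaults encode the Dutch projection used for
#' the telehealth decision: 160,000 patients in 2018 growing by 5,000 per
#' year to 255,000 in 2037 (the increment itself follows from the national
#' estimates of 130,000 patients in 2012 and 195,000 by 2025).
#'
#' @param base Patients in the first projection year (> 0).
#' @param increment Additional patients per year.
#' @param years Projection length (>= 1).
#' @param start_year First calendar year.
#' @return A data frame of class `hfvoi_projection` with columns `year`,
#'   `t` (0-based), `count`.
#' @export
#' @examples
#' proj <- incidence_projection()
#' range(proj$count) # 160,000 to 255,000
incidence_projection <- function(base = 160000, increment = 5000,
                                 years = 20L, start_year = 2018L) {
  if (base <= 0) stop("base must be positive", call. = FALSE)
  if (years < 1) stop("years must be at least 1", call. = FALSE)
  t <- seq_len(years) - 1L
  structure(data.frame(year = start_year + t, t = t,
                       count = base + increment * t),
            class = c("hfvoi_projection", "data.frame"))
}

#' Annual increment implied by two incidence estimates
#'
#' @param count_from,count_to Patient counts at two calendar years.
#' @param year_from,year_to The corresponding years.
#' @return Patients per year.
#' @export
#' @examples
#' implied_increment(130000, 195000, 2012, 2025) # 5,000 per year
implied_increment <- function(count_from, count_to, year_from, year_to) {
  if (year_to <= year_from) stop("year_to must exceed year_from",
                                 call. = FALSE)
  (count_to - count_from) / (year_to - year_from)
}

#' Discounted effective population
#'
#' The effective population over the technology's useful lifetime is the
#' discounted sum of yearly incident patients,
#' `sum_t count[t] / (1 + d)^t`. By default the first projection year is
#' undiscounted (`t = 0` start); `first_year_discounted = TRUE` gives the
#' variant where discounting starts in year one. Reported populations are
#' rounded half-up to whole patients at the reporting boundary only.
#'
#' @param projection From [incidence_projection()].
#' @param discount_rate Annual discount rate in `[0, 1)` (default 4\%, the
#'   cost discount rate, since value of information is monetary).
#' @param first_year_discounted Use the `t = 1` start convention.
#' @return A list of class `hfvoi_population`: `total_undiscounted`,
#'   `effective` (rounded), `effective_exact`, `discount_rate`.
#' @export
#' @examples
#' effective_population(incidence_projection(), 0.04)$effective # 2,841,567
effective_population <- function(projection, discount_rate = 0.04,
                                 first_year_discounted = FALSE) {
  if (discount_rate < 0 || discount_rate >= 1) {
    stop("discount_rate must lie in [0, 1)", call. = FALSE)
  }
  expo <- projection$t + as.integer(first_year_discounted)
  eff <- sum(projection$count / (1 + discount_rate)^expo)
  structure(list(
    total_undiscounted = sum(projection$count),
    effective = round_half_up(eff),
    effective_exact = eff,
    discount_rate = discount_rate,
    first_year_discounted = first_year_discounted
  ), class = "hfvoi_population")
}

#' @export
print.hfvoi_population <- function(x, ...) {
  cat(sprintf(
    "<hfvoi_population> total %s, effective %s (discounted at %.1f%%)\n",
    format(x$total_undiscounted, big.mark = ","),
    format(x$effective, big.mark = ","), 100 * x$discount_rate))
  invisible(x)
}

#' Effective population of a disease-severity subgroup
#'
#' Scales the reported effective population by the subgroup fraction and
#' rounds half-up; used for the NYHA IV analysis with the trial's initial
#' NYHA IV share of 7.32\%.
#'
#' @param pop From [effective_population()].
#' @param fraction Subgroup share in `[0, 1]`.
#' @return Patients (integer-valued).
#' @export
#' @examples
#' pop <- effective_population(incidence_projection(), 0.04)
#' subgroup_population(pop, 0.0732) # 208,003
subgroup_population <- function(pop, fraction) {
  if (fraction < 0 || fraction > 1) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  round_half_up(pop$effective * fraction)
}

#' Scale per-patient value of information to the population
#'
#' Multiplies a per-patient EVPI or EVPPI value (EUR) by the effective
#' population. The cost discount rate is used in the effective population
#' because the payoff is monetary (net monetary benefit).
#'
#' @param per_patient Per-patient value(s), EUR; vectorized.
#' @param pop From [effective_population()], or a plain patient count.
#' @return Population value(s), EUR.
#' @export
population_voi <- function(per_patient, pop) {
  n_eff <- if (inherits(pop, "hfvoi_population")) pop$effective else pop
  per_patient * n_eff
}
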