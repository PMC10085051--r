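# Hospital carrying capacity and capacity-derived referral rates. A
# hospital's carrying capacity C = beds * 1000 * k / N converts beds into a
# servable population using an occupancy (bearing-capacity) coefficient k
# and a beds-per-1000-residents planning norm N. A tier's referral rate is
# the median, over that tier's service regions, of capacity divided by
# resident population, clipped to [0, 1].

#' Beds-per-1000 planning norms
#'
#' National planning norms for hospital beds per 1000 permanent residents:
#' 6 overall, 1.2 for primary medical institutions, 3.3 for public
#' hospitals.
#'
#' @return Named list `total`, `primary`, `public`.
#' @export
capacity_norms <- function() {
  list(total = 6, primary = 1.2, public = 3.3)
}

#' Carrying capacity of a hospital
#'
#' Converts a bed count into the number of residents the hospital can carry:
#' `C = beds * 1000 * k / n_per_1000`.
#'
#' @param beds Number of beds (>= 0); vectorized.
#' @param k Bearing-capacity (occupancy) coefficient, > 0.
#' @param n_per_1000 Beds-per-1000-residents norm, > 0 (see
#'   [capacity_norms()]).
#' @return Carrying capacity in persons.
#' @export
#' @examples
#' carrying_capacity(330, k = 0.8, n_per_1000 = 3.3)
carrying_capacity <- function(beds, k, n_per_1000) {
  if (any(!is.finite(beds)) || any(beds < 0)) {
    abort("beds must be finite and non-negative")
  }
  if (!is.finite(k) || k <= 0) abort("k must be positive")
  if (!is.finite(n_per_1000) || n_per_1000 <= 0) {
    abort("n_per_1000 must be positive")
  }
  beds * 1000 * k / n_per_1000
}

#' Referral rate from regional carrying capacities
#'
#' A tier's referral rate is the median over its service regions of the
#' ratio of tier carrying capacity to resident population. Ratios are
#' clipped at 1 before taking the median (a referral rate cannot exceed
#' 100%); the median of an even count is the mean of the two middle ratios.
#'
#' @param capacity Named numeric vector: carrying capacity per region.
#' @param population Named numeric vector over the same regions, all > 0.
#' @return A single rate in `[0, 1]`.
#' @export
#' @examples
#' referral_rate(c(a = 4000, b = 10000, c = 16000),
#'               c(a = 20000, b = 20000, c = 20000))
referral_rate <- function(capacity, population) {
  if (length(capacity) == 0) {
    abort("cannot derive a referral rate from zero regions")
  }
  if (!setequal(names(capacity), names(population)) ||
      length(capacity) != length(population)) {
    abort("capacity and population must cover the same regions")
  }
  population <- population[names(capacity)]
  if (any(population <= 0)) {
    abort(paste0("zero or negative population in region(s): ",
                 paste(names(population)[population <= 0], collapse = ", ")))
  }
  ratios <- pmin(capacity / population, 1)
  median(ratios)
}

.scenario_names <- c("business_as_usual", "general_event", "major_event")

# Packaged scenario constants. Occupancy coefficients for the high-tier
# hospitals rise from normal operation (80%) through full capacity (100%)
# to overload (120%); the published referral-rate defaults rise with them.
# The primary->municipal direct referral rate is fixed at 10% throughout.
.scenario_defaults <- list(
  business_as_usual = list(k_primary = 1.0, k_county = 0.8,
                           k_municipal = 0.8, alpha = 0.43, beta = 0.10,
                           gamma = 0.63),
  general_event     = list(k_primary = 1.0, k_county = 1.0,
                           k_municipal = 1.0, alpha = 0.54, beta = 0.10,
                           gamma = 0.67),
  major_event       = list(k_primary = 1.0, k_county = 1.2,
                           k_municipal = 1.2, alpha = 0.65, beta = 0.10,
                           gamma = 0.70)
)

#' Scenario configuration
#'
#' Returns the packaged configuration of one of the three public-health
#' scenarios: `business_as_usual` (county/municipal occupancy coefficient
#' 0.8, referral rates alpha = 0.43 primary->county, gamma = 0.63
#' county->municipal), `general_event` (k = 1.0, alpha = 0.54,
#' gamma = 0.67), and `major_event` (k = 1.2, alpha = 0.65, gamma = 0.70).
#' The direct primary->municipal rate beta is 0.10 in every scenario.
#' Individual fields can be overridden; overrides are re-validated.
#'
#' @param name One of `"business_as_usual"`, `"general_event"`,
#'   `"major_event"`.
#' @param ... Named overrides among `k_primary`, `k_county`, `k_municipal`,
#'   `alpha`, `beta`, `gamma`.
#' @return A list of class `fca_scenario`.
#' @export
#' @examples
#' scenario("major_event")$k_county
scenario <- function(name, ...) {
  if (length(name) != 1 || !name %in% .scenario_names) {
    abort(paste0("unknown scenario name: ", paste(name, collapse = ", "),
                 " (expected one of ",
                 paste(.scenario_names, collapse = ", "), ")"),
          class = "hierfca_vocabulary_error")
  }
  cfg <- .scenario_defaults[[name]]
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0) {
    abort(paste0("unknown scenario field(s): ", paste(bad, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  cfg$name <- name
  validate_scenario(cfg)
  structure(cfg, class = "fca_scenario")
}

validate_scenario <- function(cfg) {
  ks <- unlist(cfg[c("k_primary", "k_county", "k_municipal")])
  if (any(!is.finite(ks)) || any(ks <= 0)) {
    abort("carrying-capacity coefficients must be positive",
          class = "hierfca_validation_error")
  }
  rates <- unlist(cfg[c("alpha", "beta", "gamma")])
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 1)) {
    abort("referral rates must lie in [0, 1]",
          class = "hierfca_validation_error")
  }
  if (cfg$alpha + cfg$beta > 1) {
    abort("alpha + beta must not exceed 1 (a patient is referred once)",
          class = "hierfca_validation_error")
  }
  invisible(cfg)
}

#' @export
print.fca_scenario <- function(x, ...) {
  cat(sprintf("<fca_scenario> %s\n", x$name))
  cat(sprintf("  k: primary %.2f / county %.2f / municipal %.2f\n",
              x$k_primary, x$k_county, x$k_municipal))
  cat(sprintf("  referral rates: alpha %.3f, beta %.3f, gamma %.3f\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Derive scenario referral rates from a study region
#'
#' Recomputes a scenario's referral rates from the region's own capacity
#' structure: `alpha` (primary -> county) is the median over counties of
#' county-tier carrying capacity divided by county population, and `gamma`
#' (county -> municipal) the median over cities of municipal-tier capacity
#' divided by city population, both using the scenario's occupancy
#' coefficients and the public-hospital beds norm. The direct rate `beta`
#' stays at its configured value.
#'
#' @param region An [fca_region] containing county and municipal hospitals.
#' @param name Scenario name (see [scenario()]).
#' @param norms Beds-per-1000 norms, see [capacity_norms()].
#' @return An `fca_scenario` with data-derived `alpha` and `gamma`.
#' @export
derive_scenario_rates <- function(region, name, norms = capacity_norms()) {
  stopifnot(inherits(region, "fca_region"))
  cfg <- scenario(name)
  alpha <- tier_referral_rate(region, "county", cfg$k_county, norms$public)
  gamma <- tier_referral_rate(region, "municipal", cfg$k_municipal,
                              norms$public)
  if (alpha > 1 - cfg$beta) {
    warn(sprintf(paste0("derived primary->county rate %.3f capped at %.3f ",
                        "so total referral from the primary tier stays ",
                        "within 100%%"), alpha, 1 - cfg$beta))
    alpha <- 1 - cfg$beta
  }
  scenario(name, alpha = alpha, gamma = gamma)
}

# Median capacity/population ratio of one tier over its service regions.
tier_referral_rate <- function(region, tier, k, n_per_1000) {
  level <- .tier_level[[tier]]
  regions <- region$units[region$units$level == level, ]
  if (nrow(regions) == 0 ||
      !any(region$hospitals$tier == tier)) {
    abort(paste0("region has no ", tier,
                 "-tier hospitals or no ", level, " units"))
  }
  pop <- regional_population(region, level)
  hosp <- region$hospitals[region$hospitals$tier == tier, ]
  beds <- tapply(hosp$beds, hosp$admin_id, sum)
  capacity <- setNames(rep(0, nrow(regions)), regions$unit_id)
  capacity[names(beds)] <- carrying_capacity(as.numeric(beds), k, n_per_1000)
  referral_rate(capacity, pop)
}

# Resident population aggregated to one administrative level.
regional_population <- function(region, level) {
  townships <- region$units[region$units$level == "township", ]
  key <- switch(level,
                township = townships$unit_id,
                county = townships$county_id,
                city = townships$city_id)
  out <- tapply(townships$population, key, sum)
  ids <- region$units$unit_id[region$units$level == level]
  res <- setNames(rep(0, length(ids)), ids)
  res[names(out)] <- as.numeric(out)
  res
}
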