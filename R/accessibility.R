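# The four-stage hierarchical 2SFCA computation.
#
# Stage 1: residents -> primary institutions. Every resident first attends a
#   primary institution in their township; the pooled township supply-demand
#   ratio R_p = beds / population is distance-decayed and selection-weighted
#   into A_ip.
# Stage 2: primary -> county hospitals. A fraction alpha of each county's
#   population is referred; R_c = county beds / (alpha * county population).
# Stage 3: primary -> municipal hospitals (direct severe-case referral).
#   The municipal demand pool is (beta + alpha*gamma) * city population,
#   pooling direct and county-routed referrals; R_m1 = city beds / pool.
# Stage 4: county -> municipal hospitals, with the same demand pool
#   (R_m2 = R_m1 under city-level pooling) but routed along county-hospital
#   -> municipal edges.
#
# Referred demand reaching a township is split across its primary
# institutions in proportion to the township's stage-1 selection weights, so
# A_ic / A_im1 / A_im2 are G_ip-weighted averages of the per-institution
# sums; with a single primary institution this reduces to the plain
# double-sum form. A stage whose demand pool is empty (zero referral flow)
# contributes zero accessibility: no flow, no access via that route.

#' Gravity distance-decay parameters
#'
#' Configures the decay function applied to within-catchment distances.
#' The power form is `max(d, floor)^(-exponent)`; the Gaussian form is
#' `exp(-d^2 / bandwidth^2)`. The floor (default 0.1 km) removes the
#' power-form singularity at zero distance.
#'
#' @param form `"power"` (default) or `"gaussian"`.
#' @param exponent Positive decay exponent for the power form (default 1).
#' @param bandwidth Positive bandwidth in km for the Gaussian form
#'   (default 10).
#' @param floor Positive distance floor in km (default 0.1).
#' @return A list of class `fca_decay`.
#' @export
decay_params <- function(form = c("power", "gaussian"), exponent = 1,
                         bandwidth = 10, floor = 0.1) {
  form <- match.arg(form)
  if (!is.finite(exponent) || exponent <= 0) {
    abort("exponent must be positive")
  }
  if (!is.finite(bandwidth) || bandwidth <= 0) {
    abort("bandwidth must be positive")
  }
  if (!is.finite(floor) || floor <= 0) abort("floor must be positive")
  structure(list(form = form, exponent = exponent, bandwidth = bandwidth,
                 floor = floor),
            class = "fca_decay")
}

#' Gravity distance decay
#'
#' @param d Distances in km (>= 0); vectorized.
#' @param params An [decay_params()] configuration.
#' @return Strictly positive, non-increasing decay weights.
#' @export
#' @examples
#' decay(2, decay_params(exponent = 1))
decay <- function(d, params = decay_params()) {
  if (any(d < 0)) abort("distances must be non-negative")
  switch(params$form,
         power = pmax(d, params$floor)^(-params$exponent),
         gaussian = exp(-d^2 / params$bandwidth^2))
}

#' Supply-demand ratio
#'
#' Beds divided by the population of the catchment, with the convention
#' that an empty demand pool yields a ratio of zero (no flow, no access via
#' that route).
#'
#' @param supply_beds Bed count (>= 0); vectorized.
#' @param demand_population Persons (>= 0); vectorized.
#' @return Ratio, zero where demand is zero.
#' @export
supply_demand_ratio <- function(supply_beds, demand_population) {
  if (any(supply_beds < 0) || any(demand_population < 0)) {
    abort("supply and demand must be non-negative")
  }
  ifelse(demand_population > 0, supply_beds / demand_population, 0)
}

# Pooled beds of one tier per serving administrative unit (0 where none).
pooled_beds <- function(region, tier, level) {
  hosp <- region$hospitals[region$hospitals$tier == tier, ]
  ids <- region$units$unit_id[region$units$level == level]
  beds <- setNames(rep(0, length(ids)), ids)
  if (nrow(hosp) > 0) {
    sums <- tapply(hosp$beds, hosp$admin_id, sum)
    beds[names(sums)] <- as.numeric(sums)
  }
  beds
}

#' Compute hierarchical accessibility for every township
#'
#' Runs the four-stage floating catchment area computation over a study
#' region under one scenario and returns the per-township decomposition
#' `A = A_p + A_c + A_m1 + A_m2`: accessibility gained at the primary tier,
#' the county tier, and the municipal tier via direct and via county-routed
#' referral. Values are dimensionless beds-per-person ratios accumulated
#' along distance-decayed, selection-weighted routes.
#'
#' @param region An [fca_region].
#' @param scen An [scenario()] configuration (or scenario name).
#' @param decay_cfg An [decay_params()] configuration.
#' @param tables An [weight_tables()] configuration.
#' @return An object of class `fca_accessibility`: a list with
#'   `townships` (per-township decomposition), `ratios` (per-hospital
#'   supply-demand ratios by stage), `referred` (referred population pools
#'   P_k1 per county and P_k2 per city), and the configuration used.
#' @export
#' @examples
#' res <- compute_accessibility(minimal_fixture(), scenario("business_as_usual"))
#' tidy(res)
compute_accessibility <- function(region, scen = scenario("business_as_usual"),
                                  decay_cfg = decay_params(),
                                  tables = weight_tables()) {
  stopifnot(inherits(region, "fca_region"))
  if (is.character(scen)) scen <- scenario(scen)
  stopifnot(inherits(scen, "fca_scenario"))

  townships <- region$units[region$units$level == "township", ]
  county_pop <- regional_population(region, "county")
  city_pop <- regional_population(region, "city")

  # demand pools: entire population at stage 1, referred fractions above
  p_k1 <- scen$alpha * county_pop
  p_k2 <- (scen$beta + scen$alpha * scen$gamma) * city_pop

  # pooled per-unit supply-demand ratios (same-tier hospitals in one
  # district are treated as a whole)
  r_p_unit <- supply_demand_ratio(pooled_beds(region, "primary", "township"),
                                  regional_population(region, "township"))
  r_c_unit <- supply_demand_ratio(pooled_beds(region, "county", "county"),
                                  p_k1)
  r_m_unit <- supply_demand_ratio(pooled_beds(region, "municipal", "city"),
                                  p_k2)

  w_ip <- edge_selection_weights(region, "ip", tables)
  w_pc <- edge_selection_weights(region, "pc", tables)
  w_pm <- edge_selection_weights(region, "pm", tables)
  w_cm <- edge_selection_weights(region, "cm", tables)

  hosp <- region$hospitals
  ratio_of <- function(ids, unit_ratios, key) {
    as.numeric(unit_ratios[key[match(ids, hosp$hospital_id)]])
  }

  # per-edge accessibility contributions R * f(d) * G
  w_ip$contrib <- ratio_of(w_ip$dest_id, r_p_unit, hosp$admin_id) *
    decay(w_ip$km, decay_cfg) * w_ip$g
  w_pc$contrib <- ratio_of(w_pc$dest_id, r_c_unit, hosp$county_id) *
    decay(w_pc$km, decay_cfg) * w_pc$g
  w_pm$contrib <- ratio_of(w_pm$dest_id, r_m_unit, hosp$city_id) *
    decay(w_pm$km, decay_cfg) * w_pm$g
  w_cm$contrib <- ratio_of(w_cm$dest_id, r_m_unit, hosp$city_id) *
    decay(w_cm$km, decay_cfg) * w_cm$g

  sum_by <- function(values, keys, all_keys) {
    out <- setNames(rep(0, length(all_keys)), all_keys)
    if (length(values) > 0) {
      sums <- tapply(values, keys, sum)
      out[names(sums)] <- as.numeric(sums)
    }
    out
  }

  prim_ids <- hosp$hospital_id[hosp$tier == "primary"]
  cnty_ids <- hosp$hospital_id[hosp$tier == "county"]

  # per primary institution: decayed, weighted upstream sums
  s2_p <- sum_by(w_pc$contrib, w_pc$origin_id, prim_ids)
  s3_p <- sum_by(w_pm$contrib, w_pm$origin_id, prim_ids)
  # per county hospital: municipal-route sum, then fold back to primaries
  # through the stage-2 selection weights G_pc
  s4_c <- sum_by(w_cm$contrib, w_cm$origin_id, cnty_ids)
  s4_p <- sum_by(w_pc$g * s4_c[w_pc$dest_id], w_pc$origin_id, prim_ids)

  # the county->municipal route carries flow only when alpha*gamma > 0
  county_route_open <- as.numeric(scen$alpha > 0 && scen$gamma > 0)

  town_ids <- townships$unit_id
  a_p <- sum_by(w_ip$contrib, w_ip$origin_id, town_ids)
  a_c <- sum_by(w_ip$g * s2_p[w_ip$dest_id], w_ip$origin_id, town_ids)
  a_m1 <- sum_by(w_ip$g * s3_p[w_ip$dest_id], w_ip$origin_id, town_ids)
  a_m2 <- county_route_open *
    sum_by(w_ip$g * s4_p[w_ip$dest_id], w_ip$origin_id, town_ids)

  township_tab <- tibble::tibble(
    unit_id = town_ids,
    county_id = townships$county_id,
    city_id = townships$city_id,
    population = townships$population,
    x_km = townships$x_km,
    y_km = townships$y_km,
    A_p = as.numeric(a_p),
    A_c = as.numeric(a_c),
    A_m1 = as.numeric(a_m1),
    A_m2 = as.numeric(a_m2),
    A = as.numeric(a_p + a_c + a_m1 + a_m2)
  )

  ratios <- dplyr::bind_rows(
    tibble::tibble(hospital_id = hosp$hospital_id[hosp$tier == "primary"],
                   stage = "R_p",
                   ratio = as.numeric(
                     r_p_unit[hosp$admin_id[hosp$tier == "primary"]])),
    tibble::tibble(hospital_id = cnty_ids, stage = "R_c",
                   ratio = as.numeric(
                     r_c_unit[hosp$county_id[hosp$tier == "county"]])),
    tibble::tibble(hospital_id = hosp$hospital_id[hosp$tier == "municipal"],
                   stage = "R_m1",
                   ratio = as.numeric(
                     r_m_unit[hosp$city_id[hosp$tier == "municipal"]])),
    tibble::tibble(hospital_id = hosp$hospital_id[hosp$tier == "municipal"],
                   stage = "R_m2",
                   ratio = as.numeric(
                     r_m_unit[hosp$city_id[hosp$tier == "municipal"]]))
  )

  referred <- dplyr::bind_rows(
    tibble::tibble(unit_id = names(p_k1), level = "county",
                   referred_population = as.numeric(p_k1)),
    tibble::tibble(unit_id = names(p_k2), level = "city",
                   referred_population = as.numeric(p_k2))
  )

  structure(
    list(townships = township_tab, ratios = ratios, referred = referred,
         scenario = scen, decay = decay_cfg, tables = tables),
    class = "fca_accessibility"
  )
}

#' @export
print.fca_accessibility <- function(x, ...) {
  cat(sprintf("<fca_accessibility> %d townships, scenario '%s'\n",
              nrow(x$townships), x$scenario$name))
  g <- glance(x)
  cat(sprintf("  mean A = %.6g, sd A = %.6g (population-sd convention)\n",
              g$mean_A, g$sd_A))
  cat(sprintf("  tier means: primary %.3g / county %.3g / municipal %.3g\n",
              mean(x$townships$A_p), mean(x$townships$A_c),
              mean(x$townships$A_m1 + x$townships$A_m2)))
  invisible(x)
}

#' @rdname compute_accessibility
#' @param x An `fca_accessibility` object.
#' @param ... Unused.
#' @method tidy fca_accessibility
#' @export
tidy.fca_accessibility <- function(x, ...) {
  x$townships
}

#' @rdname compute_accessibility
#' @method glance fca_accessibility
#' @export
glance.fca_accessibility <- function(x, ...) {
  a <- x$townships$A
  w <- x$townships$population
  tibble::tibble(
    scenario = x$scenario$name,
    n_townships = length(a),
    mean_A = mean(a),
    sd_A = pop_sd(a),
    weighted_mean_A = if (sum(w) > 0) sum(a * w) / sum(w) else NA_real_,
    min_A = min(a),
    max_A = max(a)
  )
}

# population standard deviation (divide by n, not n-1)
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
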