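# Seeded synthetic study regions. The generator emulates the statistical
# shape of the real inputs the model consumes -- a nested township/county/
# city hierarchy with heavy-tailed township populations, an inverted-
# triangle bed distribution (municipal >> county >> primary per facility),
# tier-correlated accreditation grades, national type-visit probabilities,
# and planar distances inflated by a detour factor standing in for
# road-network circuity.

.default_grade_probs <- list(
  primary = c(under_secondary = 0.70, secondary = 0.25,
              grade_a_secondary = 0.05, tertiary = 0, grade_a_tertiary = 0),
  county = c(under_secondary = 0.05, secondary = 0.35,
             grade_a_secondary = 0.40, tertiary = 0.15,
             grade_a_tertiary = 0.05),
  municipal = c(under_secondary = 0, secondary = 0.05,
                grade_a_secondary = 0.15, tertiary = 0.35,
                grade_a_tertiary = 0.45)
)

#' Synthetic-region generator configuration
#'
#' Parameters of [generate_region()]. Defaults give a compact region with
#' realistic structure: lognormal township populations (median about
#' 30,000), bed counts per facility of roughly 5-30 (primary), 50-500 (county) and
#' 300-2000 (municipal), grades skewing higher with tier, hospital types
#' drawn with the packaged national visit shares, and one designated
#' capital city whose hospitals carry a bed multiplier.
#'
#' @param n_cities,counties_per_city,townships_per_county Hierarchy shape.
#' @param pop_meanlog,pop_sdlog Lognormal parameters of township population.
#' @param beds_range Named list of `c(min, max)` bed ranges per tier;
#'   facility bed counts are drawn log-uniformly within the range.
#' @param grade_probs Named list of per-tier grade probability vectors.
#' @param type_probs Type sampling probabilities (default: the packaged
#'   national visit shares, normalised for sampling).
#' @param primary_per_township Poisson mean of primary institutions per
#'   township (zero allowed: such townships have no entry point).
#' @param county_per_county,municipal_per_city Poisson means of facility
#'   counts (at least one is always placed).
#' @param extent_km Side of the square study area in km.
#' @param detour Detour factor for Euclidean distances.
#' @param capital_concentration Bed multiplier applied to hospitals of the
#'   first city, mimicking capital-city resource concentration.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `fca_region_config`.
#' @export
region_config <- function(n_cities = 3,
                          counties_per_city = 3,
                          townships_per_county = 4,
                          pop_meanlog = log(30000),
                          pop_sdlog = 0.7,
                          beds_range = list(primary = c(5, 30),
                                            county = c(50, 500),
                                            municipal = c(300, 2000)),
                          grade_probs = .default_grade_probs,
                          type_probs = .type_weights,
                          primary_per_township = 2,
                          county_per_county = 1.5,
                          municipal_per_city = 1.5,
                          extent_km = 300,
                          detour = 1.3,
                          capital_concentration = 1.5,
                          seed = 42) {
  cfg <- list(n_cities = n_cities, counties_per_city = counties_per_city,
              townships_per_county = townships_per_county,
              pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
              beds_range = beds_range, grade_probs = grade_probs,
              type_probs = type_probs,
              primary_per_township = primary_per_township,
              county_per_county = county_per_county,
              municipal_per_city = municipal_per_city,
              extent_km = extent_km, detour = detour,
              capital_concentration = capital_concentration, seed = seed)
  counts <- c(n_cities, counties_per_city, townships_per_county)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort("hierarchy counts must be integers >= 1",
          class = "hierfca_validation_error")
  }
  if (!all(.hospital_tiers %in% names(beds_range)) ||
      any(vapply(beds_range, function(r) r[1] < 1 || r[2] < r[1],
                 logical(1)))) {
    abort("beds_range must give a valid c(min, max) per tier",
          class = "hierfca_validation_error")
  }
  if (abs(sum(type_probs / sum(type_probs)) - 1) > 1e-9 ||
      any(type_probs < 0)) {
    abort("type_probs must be non-negative", class = "hierfca_validation_error")
  }
  if (pop_sdlog < 0 || extent_km <= 0 || detour < 1 ||
      capital_concentration < 1) {
    abort("invalid generator parameter", class = "hierfca_validation_error")
  }
  structure(cfg, class = "fca_region_config")
}

#' Generate a synthetic study region
#'
#' Draws a nested administrative hierarchy, heavy-tailed township
#' populations, and a three-tier hospital registry from a seeded generator,
#' and assembles them into a validated [fca_region]. Fully reproducible:
#' the same configuration (including seed) yields an identical region.
#'
#' @param config An [region_config()].
#' @return An [fca_region].
#' @export
#' @examples
#' region <- generate_region(region_config(seed = 1))
generate_region <- function(config = region_config()) {
  stopifnot(inherits(config, "fca_region_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  cities <- tibble::tibble(
    unit_id = sprintf("city%02d", seq_len(config$n_cities)),
    level = "city",
    parent_id = NA_character_,
    population = 0,
    x_km = runif(config$n_cities, 0, config$extent_km),
    y_km = runif(config$n_cities, 0, config$extent_km)
  )
  counties <- purrr::map_dfr(seq_len(nrow(cities)), function(ci) {
    n <- config$counties_per_city
    tibble::tibble(
      unit_id = sprintf("%s_cnty%02d", cities$unit_id[ci], seq_len(n)),
      level = "county",
      parent_id = cities$unit_id[ci],
      population = 0,
      x_km = cities$x_km[ci] +
        rnorm(n, 0, config$extent_km / (4 * config$n_cities)),
      y_km = cities$y_km[ci] +
        rnorm(n, 0, config$extent_km / (4 * config$n_cities))
    )
  })
  townships <- purrr::map_dfr(seq_len(nrow(counties)), function(ki) {
    n <- config$townships_per_county
    tibble::tibble(
      unit_id = sprintf("%s_twn%02d", counties$unit_id[ki], seq_len(n)),
      level = "township",
      parent_id = counties$unit_id[ki],
      population = round(rlnorm(n, config$pop_meanlog, config$pop_sdlog)),
      x_km = counties$x_km[ki] + rnorm(n, 0, 6),
      y_km = counties$y_km[ki] + rnorm(n, 0, 6)
    )
  })
  units <- dplyr::bind_rows(cities, counties, townships)

  capital <- cities$unit_id[1]
  type_p <- config$type_probs / sum(config$type_probs)

  sample_hospitals <- function(host, tier, n_mean, min_n) {
    purrr::map_dfr(seq_len(nrow(host)), function(i) {
      n <- max(min_n, rpois(1, n_mean))
      if (n == 0) return(tibble::tibble())
      rng <- config$beds_range[[tier]]
      beds <- round(exp(runif(n, log(rng[1]), log(rng[2]))))
      gp <- config$grade_probs[[tier]]
      grade <- sample(names(gp), n, replace = TRUE, prob = gp)
      type <- sample(names(type_p), n, replace = TRUE, prob = type_p)
      tibble::tibble(
        hospital_id = sprintf("%s_%s%02d", host$unit_id[i],
                              substr(tier, 1, 4), seq_len(n)),
        tier = tier,
        admin_id = host$unit_id[i],
        beds = beds,
        grade = grade,
        type = type,
        x_km = host$x_km[i] + rnorm(n, 0, 2),
        y_km = host$y_km[i] + rnorm(n, 0, 2),
        city_of = host_city(host$unit_id[i], units)
      )
    })
  }

  hospitals <- dplyr::bind_rows(
    sample_hospitals(townships, "primary", config$primary_per_township, 0),
    sample_hospitals(counties, "county", config$county_per_county, 1),
    sample_hospitals(cities, "municipal", config$municipal_per_city, 1)
  )
  hospitals$beds <- ifelse(hospitals$city_of == capital,
                           round(hospitals$beds *
                                   config$capital_concentration),
                           hospitals$beds)
  hospitals$city_of <- NULL

  suppressWarnings(
    fca_region(units, hospitals, distances = NULL, detour = config$detour)
  )
}

# city ancestor of a unit id (works for any level)
host_city <- function(unit_id, units) {
  lvl <- units$level[match(unit_id, units$unit_id)]
  while (lvl != "city") {
    unit_id <- units$parent_id[match(unit_id, units$unit_id)]
    lvl <- units$level[match(unit_id, units$unit_id)]
  }
  unit_id
}

# save/restore the global RNG state so generation is a pure function
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Minimal deterministic fixture region
#'
#' A one-city / one-county / one-township region with one hospital per tier,
#' small enough to evaluate the whole four-stage computation by hand:
#' township of 10,000 residents at the origin; a 12-bed secondary general
#' primary institution co-located with the township (distance resolves to
#' the decay floor); a 100-bed grade-A-secondary general county hospital
#' 10 km away; a 500-bed grade-A-tertiary general municipal hospital 30 km
#' away. Distances are Euclidean with detour factor 1 so the printed
#' geometry is exact.
#'
#' @return An [fca_region] with exactly 3 hospitals.
#' @export
minimal_fixture <- function() {
  units <- tibble::tibble(
    unit_id = c("c1", "k1", "t1"),
    level = c("city", "county", "township"),
    parent_id = c(NA, "c1", "k1"),
    population = c(0, 0, 10000),
    x_km = c(0, 0, 0),
    y_km = c(0, 0, 0)
  )
  hospitals <- tibble::tibble(
    hospital_id = c("hp1", "hc1", "hm1"),
    tier = c("primary", "county", "municipal"),
    admin_id = c("t1", "k1", "c1"),
    beds = c(12, 100, 500),
    grade = c("secondary", "grade_a_secondary", "grade_a_tertiary"),
    type = c("general", "general", "general"),
    x_km = c(0, 10, 30),
    y_km = c(0, 0, 0)
  )
  fca_region(units, hospitals, distances = NULL, detour = 1)
}

#' Packaged demo region
#'
#' The default synthetic region used in examples and scenario comparisons:
#' [generate_region()] at the default configuration (3 cities x 3 counties
#' x 4 townships, seed 42).
#'
#' @param seed Generator seed (default 42).
#' @return An [fca_region].
#' @export
demo_region <- function(seed = 42) {
  generate_region(region_config(seed = seed))
}
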