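# Study-region container: administrative units, hospitals, and the four
# origin-destination distance sets (township->primary, primary->county,
# primary->municipal, county-hospital->municipal). Catchments are defined by
# administrative containment: a primary institution serves its township, a
# county hospital its county, a municipal hospital its city. Distances are
# only needed for within-catchment pairs and enter the model through the
# decay function, not through a threshold.

#' Assemble and validate a study region
#'
#' Builds the container holding the nested administrative hierarchy
#' (townships within counties within cities), the three-tier hospital
#' registry, and the within-catchment origin-destination distances. When no
#' distance table is supplied, planar Euclidean distances are computed from
#' the `x_km` / `y_km` coordinates and multiplied by a detour factor that
#' stands in for road-network circuity.
#'
#' @param units Data frame with columns `unit_id`, `level` (one of
#'   `"township"`, `"county"`, `"city"`), `parent_id` (`NA` for cities),
#'   `population`, and optionally `x_km`, `y_km`.
#' @param hospitals Data frame with columns `hospital_id`, `tier` (one of
#'   `"primary"`, `"county"`, `"municipal"`), `admin_id` (the township /
#'   county / city the hospital serves), `beds`, `grade`, `type`, and
#'   optionally `x_km`, `y_km`.
#' @param distances Optional data frame with columns `origin_id`, `dest_id`,
#'   `pair_kind` (one of `"ip"`, `"pc"`, `"pm"`, `"cm"`), `km`, covering
#'   every within-catchment pair. If `NULL`, distances are derived from
#'   coordinates.
#' @param detour Detour factor applied to Euclidean distances when deriving
#'   them from coordinates (default 1.3).
#' @return An object of class `fca_region`: a list with tibbles `units`
#'   (augmented with resolved `county_id` / `city_id`), `hospitals`
#'   (augmented likewise) and `distances`.
#' @export
#' @examples
#' region <- minimal_fixture()
#' region$units
fca_region <- function(units, hospitals, distances = NULL, detour = 1.3) {
  units <- tibble::as_tibble(units)
  hospitals <- tibble::as_tibble(hospitals)
  validate_units(units)
  validate_hospitals(hospitals, units)

  units <- resolve_unit_lineage(units)
  hospitals <- resolve_hospital_lineage(hospitals, units)

  if (is.null(distances)) {
    if (anyNA(units$x_km) || anyNA(units$y_km) ||
        anyNA(hospitals$x_km) || anyNA(hospitals$y_km)) {
      abort("no distance table supplied and some coordinates are missing")
    }
    if (!is.numeric(detour) || length(detour) != 1 || detour < 1) {
      abort("detour factor must be a single number >= 1")
    }
    distances <- derive_distances(units, hospitals, detour)
  } else {
    distances <- tibble::as_tibble(distances)
    validate_distances(distances, units, hospitals)
  }

  region <- structure(
    list(units = units, hospitals = hospitals, distances = distances),
    class = "fca_region"
  )
  orphan <- townships_without_primary(region)
  if (length(orphan) > 0) {
    warn(paste0(length(orphan), " township(s) have no primary institution ",
                "and get zero accessibility: ",
                paste(head(orphan, 5), collapse = ", "),
                if (length(orphan) > 5) ", ..." else ""))
  }
  region
}

#' @export
print.fca_region <- function(x, ...) {
  n_lvl <- table(factor(x$units$level, levels = .unit_levels))
  n_tier <- table(factor(x$hospitals$tier, levels = .hospital_tiers))
  cat("<fca_region>\n")
  cat(sprintf("  units:     %d townships / %d counties / %d cities (pop %s)\n",
              n_lvl[["township"]], n_lvl[["county"]], n_lvl[["city"]],
              format(sum(x$units$population[x$units$level == "township"]),
                     big.mark = ",")))
  cat(sprintf("  hospitals: %d primary / %d county / %d municipal (%d beds)\n",
              n_tier[["primary"]], n_tier[["county"]], n_tier[["municipal"]],
              sum(x$hospitals$beds)))
  cat(sprintf("  distances: %d within-catchment pairs\n", nrow(x$distances)))
  invisible(x)
}

validate_units <- function(units) {
  required <- c("unit_id", "level", "parent_id", "population")
  missing_cols <- setdiff(required, names(units))
  if (length(missing_cols) > 0) {
    abort(paste0("units table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hierfca_validation_error")
  }
  bad_level <- setdiff(unique(units$level), .unit_levels)
  if (length(bad_level) > 0) {
    abort(paste0("unknown unit level token(s): ",
                 paste(bad_level, collapse = ", ")),
          class = "hierfca_validation_error")
  }
  if (anyDuplicated(units$unit_id)) {
    abort("duplicate unit_id in units table",
          class = "hierfca_validation_error")
  }
  if (any(!is.finite(units$population)) || any(units$population < 0)) {
    bad <- units$unit_id[!is.finite(units$population) | units$population < 0]
    abort(paste0("negative or non-finite population for unit(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "hierfca_validation_error")
  }
  parent_level <- c(township = "county", county = "city")
  for (lvl in names(parent_level)) {
    rows <- units[units$level == lvl, ]
    if (anyNA(rows$parent_id)) {
      abort(paste0(lvl, " unit(s) without parent_id: ",
                   paste(head(rows$unit_id[is.na(rows$parent_id)], 5),
                         collapse = ", ")),
            class = "hierfca_validation_error")
    }
    parents <- units$level[match(rows$parent_id, units$unit_id)]
    bad <- rows$unit_id[is.na(parents) | parents != parent_level[[lvl]]]
    if (length(bad) > 0) {
      abort(paste0(lvl, " unit(s) whose parent_id does not resolve to a ",
                   parent_level[[lvl]], ": ",
                   paste(head(bad, 5), collapse = ", ")),
            class = "hierfca_validation_error")
    }
  }
  invisible(units)
}

validate_hospitals <- function(hospitals, units) {
  required <- c("hospital_id", "tier", "admin_id", "beds", "grade", "type")
  missing_cols <- setdiff(required, names(hospitals))
  if (length(missing_cols) > 0) {
    abort(paste0("hospitals table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hierfca_validation_error")
  }
  bad_tier <- setdiff(unique(hospitals$tier), .hospital_tiers)
  if (length(bad_tier) > 0) {
    abort(paste0("unknown hospital tier token(s): ",
                 paste(bad_tier, collapse = ", ")),
          class = "hierfca_validation_error")
  }
  if (anyDuplicated(hospitals$hospital_id)) {
    abort("duplicate hospital_id in hospitals table",
          class = "hierfca_validation_error")
  }
  grade_coefficient(hospitals$grade)   # vocabulary check
  type_weight(hospitals$type)
  if (any(!is.finite(hospitals$beds)) || any(hospitals$beds < 0)) {
    bad <- hospitals$hospital_id[!is.finite(hospitals$beds) |
                                   hospitals$beds < 0]
    abort(paste0("negative or non-finite beds for hospital(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "hierfca_validation_error")
  }
  admin_level <- units$level[match(hospitals$admin_id, units$unit_id)]
  expected <- unname(.tier_level[hospitals$tier])
  bad <- hospitals$hospital_id[is.na(admin_level) | admin_level != expected]
  if (length(bad) > 0) {
    abort(paste0("hospital(s) whose admin_id does not resolve to a unit of ",
                 "the tier-matching level: ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "hierfca_validation_error")
  }
  invisible(hospitals)
}

# Attach county_id / city_id to every unit (and keep coordinates columns).
resolve_unit_lineage <- function(units) {
  if (!"x_km" %in% names(units)) units$x_km <- NA_real_
  if (!"y_km" %in% names(units)) units$y_km <- NA_real_
  parent <- units$parent_id[match(units$unit_id, units$unit_id)]
  county_id <- ifelse(units$level == "township", units$parent_id,
                      ifelse(units$level == "county", units$unit_id,
                             NA_character_))
  city_of_county <- units$parent_id[match(county_id, units$unit_id)]
  city_id <- ifelse(units$level == "city", units$unit_id, city_of_county)
  units$county_id <- county_id
  units$city_id <- city_id
  units
}

resolve_hospital_lineage <- function(hospitals, units) {
  if (!"x_km" %in% names(hospitals)) hospitals$x_km <- NA_real_
  if (!"y_km" %in% names(hospitals)) hospitals$y_km <- NA_real_
  idx <- match(hospitals$admin_id, units$unit_id)
  hospitals$county_id <- units$county_id[idx]
  hospitals$city_id <- units$city_id[idx]
  hospitals$township_id <- ifelse(hospitals$tier == "primary",
                                  hospitals$admin_id, NA_character_)
  hospitals
}

# Within-catchment origin-destination pairs under containment semantics.
catchment_pairs <- function(units, hospitals) {
  townships <- units[units$level == "township", ]
  prim <- hospitals[hospitals$tier == "primary", ]
  cnty <- hospitals[hospitals$tier == "county", ]
  muni <- hospitals[hospitals$tier == "municipal", ]

  ip <- dplyr::inner_join(
    dplyr::select(townships, origin_id = "unit_id", key = "unit_id"),
    dplyr::select(prim, dest_id = "hospital_id", key = "admin_id"),
    by = "key", relationship = "many-to-many")
  pc <- dplyr::inner_join(
    dplyr::select(prim, origin_id = "hospital_id", key = "county_id"),
    dplyr::select(cnty, dest_id = "hospital_id", key = "county_id"),
    by = "key", relationship = "many-to-many")
  pm <- dplyr::inner_join(
    dplyr::select(prim, origin_id = "hospital_id", key = "city_id"),
    dplyr::select(muni, dest_id = "hospital_id", key = "city_id"),
    by = "key", relationship = "many-to-many")
  cm <- dplyr::inner_join(
    dplyr::select(cnty, origin_id = "hospital_id", key = "city_id"),
    dplyr::select(muni, dest_id = "hospital_id", key = "city_id"),
    by = "key", relationship = "many-to-many")

  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(ip, -"key"), pair_kind = "ip"),
    dplyr::mutate(dplyr::select(pc, -"key"), pair_kind = "pc"),
    dplyr::mutate(dplyr::select(pm, -"key"), pair_kind = "pm"),
    dplyr::mutate(dplyr::select(cm, -"key"), pair_kind = "cm")
  )
}

derive_distances <- function(units, hospitals, detour) {
  pairs <- catchment_pairs(units, hospitals)
  coords <- dplyr::bind_rows(
    dplyr::select(units, id = "unit_id", "x_km", "y_km"),
    dplyr::select(hospitals, id = "hospital_id", "x_km", "y_km")
  )
  oi <- match(pairs$origin_id, coords$id)
  di <- match(pairs$dest_id, coords$id)
  pairs$km <- detour * sqrt((coords$x_km[oi] - coords$x_km[di])^2 +
                              (coords$y_km[oi] - coords$y_km[di])^2)
  pairs[, c("origin_id", "dest_id", "pair_kind", "km")]
}

validate_distances <- function(distances, units, hospitals) {
  required <- c("origin_id", "dest_id", "pair_kind", "km")
  missing_cols <- setdiff(required, names(distances))
  if (length(missing_cols) > 0) {
    abort(paste0("distances table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hierfca_validation_error")
  }
  bad_kind <- setdiff(unique(distances$pair_kind), c("ip", "pc", "pm", "cm"))
  if (length(bad_kind) > 0) {
    abort(paste0("unknown pair_kind token(s): ",
                 paste(bad_kind, collapse = ", ")),
          class = "hierfca_validation_error")
  }
  if (any(!is.finite(distances$km)) || any(distances$km < 0)) {
    abort("distances must be finite and non-negative",
          class = "hierfca_validation_error")
  }
  needed <- catchment_pairs(units, hospitals)
  key <- function(d) paste(d$pair_kind, d$origin_id, d$dest_id)
  absent <- needed[!(key(needed) %in% key(distances)), ]
  if (nrow(absent) > 0) {
    abort(paste0(nrow(absent), " within-catchment pair(s) missing from the ",
                 "distance table, e.g. ", absent$pair_kind[1], " ",
                 absent$origin_id[1], " -> ", absent$dest_id[1]),
          class = "hierfca_validation_error")
  }
  if (anyDuplicated(key(distances))) {
    abort("duplicate origin/dest/pair_kind rows in the distance table",
          class = "hierfca_validation_error")
  }
  invisible(distances)
}

townships_without_primary <- function(region) {
  townships <- region$units$unit_id[region$units$level == "township"]
  with_primary <- unique(
    region$hospitals$admin_id[region$hospitals$tier == "primary"])
  setdiff(townships, with_primary)
}

#' Read a study region from CSV files
#'
#' Reads the `units.csv` / `hospitals.csv` (and optionally `distances.csv`)
#' schema and returns a validated [fca_region]. When `distances_path` is
#' `NULL`, every unit and hospital must carry coordinates and distances are
#' computed as Euclidean distance times the detour factor.
#'
#' @param units_path Path to the units CSV (`unit_id, level, parent_id,
#'   population, x_km, y_km`).
#' @param hospitals_path Path to the hospitals CSV (`hospital_id, tier,
#'   admin_id, beds, grade, type, x_km, y_km`).
#' @param distances_path Optional path to the long-format distances CSV
#'   (`origin_id, dest_id, pair_kind, km`).
#' @inheritParams fca_region
#' @return An [fca_region].
#' @export
read_region <- function(units_path, hospitals_path, distances_path = NULL,
                        detour = 1.3) {
  units <- readr::read_csv(
    units_path,
    col_types = readr::cols(
      unit_id = "c", level = "c", parent_id = "c",
      population = "d", .default = "d"))
  hospitals <- readr::read_csv(
    hospitals_path,
    col_types = readr::cols(
      hospital_id = "c", tier = "c", admin_id = "c", beds = "d",
      grade = "c", type = "c", .default = "d"))
  distances <- NULL
  if (!is.null(distances_path)) {
    distances <- readr::read_csv(
      distances_path,
      col_types = readr::cols(origin_id = "c", dest_id = "c",
                              pair_kind = "c", km = "d"))
  }
  fca_region(units, hospitals, distances, detour = detour)
}

#' Write a study region to CSV files
#'
#' Writes `units.csv`, `hospitals.csv` and `distances.csv` into a directory,
#' in the schema accepted by [read_region()].
#'
#' @param region An [fca_region].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_region <- function(region, dir) {
  stopifnot(inherits(region, "fca_region"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(units = file.path(dir, "units.csv"),
             hospitals = file.path(dir, "hospitals.csv"),
             distances = file.path(dir, "distances.csv"))
  readr::write_csv(
    region$units[, c("unit_id", "level", "parent_id", "population",
                     "x_km", "y_km")],
    paths[["units"]])
  readr::write_csv(
    region$hospitals[, c("hospital_id", "tier", "admin_id", "beds",
                         "grade", "type", "x_km", "y_km")],
    paths[["hospitals"]])
  readr::write_csv(region$distances, paths[["distances"]])
  invisible(paths)
}

#' Write accessibility results to disk
#'
#' Writes the per-township accessibility decomposition to
#' `accessibility.csv` and, when township coordinates are available, a
#' point-geometry `accessibility.geojson` carrying the same attributes.
#'
#' @param result An [fca_accessibility] object from
#'   [compute_accessibility()].
#' @param dir Output directory (created if absent).
#' @param geojson Write the GeoJSON companion when coordinates are present
#'   (default `TRUE`).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(result, dir, geojson = TRUE) {
  stopifnot(inherits(result, "fca_accessibility"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- tidy(result)
  csv_path <- file.path(dir, "accessibility.csv")
  readr::write_csv(tab, csv_path)
  paths <- c(csv = csv_path)
  if (geojson && !anyNA(tab$x_km) && !anyNA(tab$y_km)) {
    gj_path <- file.path(dir, "accessibility.geojson")
    features <- purrr::pmap(tab, function(unit_id, x_km, y_km, ...) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(x_km, y_km)),
           properties = c(list(unit_id = unit_id), list(...)))
    })
    jsonlite::write_json(
      list(type = "FeatureCollection", features = features),
      gj_path, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, geojson = gj_path)
  }
  invisible(paths)
}

#' Read accessibility results back from CSV
#'
#' @param path Path to an `accessibility.csv` written by [write_results()].
#' @return A tibble with the per-township decomposition.
#' @export
read_results <- function(path) {
  readr::read_csv(path, col_types = readr::cols(unit_id = "c",
                                                county_id = "c",
                                                city_id = "c",
                                                .default = "d"))
}
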