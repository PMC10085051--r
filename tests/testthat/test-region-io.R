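# Region container, validation, and CSV round-trips.

test_that("distances derived from coordinates are Euclidean times detour", {
  region <- two_township_region(detour = 1.3)
  d_ip <- region$distances[region$distances$pair_kind == "ip", ]
  # 2 townships x (their own primary only, containment): 2 pairs
  expect_equal(nrow(d_ip), 2)
  expect_equal(d_ip$km[d_ip$origin_id == "t1" & d_ip$dest_id == "p1"],
               1.3 * 1)
  expect_equal(d_ip$km[d_ip$origin_id == "t2" & d_ip$dest_id == "p2"],
               1.3 * 1)
  d_pc <- region$distances[region$distances$pair_kind == "pc", ]
  expect_equal(sort(d_pc$origin_id), c("p1", "p2"))
  expect_equal(d_pc$km[d_pc$origin_id == "p1"], 1.3 * 5, tolerance = 1e-12)
})

test_that("catchments follow administrative containment, not distance", {
  units <- tibble::tibble(
    unit_id = c("c1", "k1", "k2", "t1", "t2"),
    level = c("city", "county", "county", "township", "township"),
    parent_id = c(NA, "c1", "c1", "k1", "k2"),
    population = c(0, 0, 0, 1000, 1000),
    x_km = c(0, 0, 0, 0, 0.5),
    y_km = c(0, 0, 0, 0, 0)
  )
  # t2's primary is right next to t1, but t1 may only use its own township's
  hospitals <- tibble::tibble(
    hospital_id = c("p2", "k1h", "k2h", "m1"),
    tier = c("primary", "county", "county", "municipal"),
    admin_id = c("t2", "k1", "k2", "c1"),
    beds = c(10, 100, 100, 500),
    grade = "secondary", type = "general",
    x_km = c(0.1, 1, 2, 3), y_km = 0
  )
  expect_warning(region <- fca_region(units, hospitals),
                 "no primary institution")
  d <- region$distances
  expect_false(any(d$pair_kind == "ip" & d$origin_id == "t1"))
  # p2 (county k2) must not reach k1's county hospital
  expect_false(any(d$pair_kind == "pc" & d$origin_id == "p2" &
                     d$dest_id == "k1h"))
  expect_true(any(d$pair_kind == "pc" & d$origin_id == "p2" &
                    d$dest_id == "k2h"))
})

test_that("validation rejects malformed inputs, naming the offender", {
  region <- two_township_region()
  u <- region$units[, c("unit_id", "level", "parent_id", "population",
                        "x_km", "y_km")]
  h <- region$hospitals[, c("hospital_id", "tier", "admin_id", "beds",
                            "grade", "type", "x_km", "y_km")]

  bad <- u; bad$level[3] <- "village"
  expect_error(fca_region(bad, h), "village",
               class = "hierfca_validation_error")

  bad <- u; bad$parent_id[3] <- "nowhere"
  expect_error(fca_region(bad, h), "t1", class = "hierfca_validation_error")

  bad <- u; bad$population[3] <- -5
  expect_error(fca_region(bad, h), "population",
               class = "hierfca_validation_error")

  bad <- h; bad$admin_id[bad$hospital_id == "k1h"] <- "t1"
  expect_error(fca_region(u, bad), "k1h",
               class = "hierfca_validation_error")

  bad <- h; bad$beds[1] <- -1
  expect_error(fca_region(u, bad), "beds",
               class = "hierfca_validation_error")

  bad <- h; bad$grade[1] <- "level-9"
  expect_error(fca_region(u, bad), "level-9")

  bad <- h; bad$type[2] <- "plastic-surgery"
  expect_error(fca_region(u, bad), "plastic-surgery")

  expect_error(fca_region(u[, -4], h), "population",
               class = "hierfca_validation_error")
})

test_that("supplied distance tables must cover every containment pair", {
  region <- two_township_region()
  d <- region$distances
  expect_silent(
    fca_region(region$units, region$hospitals, distances = d))
  expect_error(
    fca_region(region$units, region$hospitals, distances = d[-1, ]),
    "missing", class = "hierfca_validation_error")
  bad <- d; bad$km[2] <- -4
  expect_error(
    fca_region(region$units, region$hospitals, distances = bad),
    "non-negative", class = "hierfca_validation_error")
})

test_that("write_region / read_region round-trips exactly", {
  dir <- withr::local_tempdir()
  region <- two_township_region()
  write_region(region, dir)
  back <- read_region(file.path(dir, "units.csv"),
                      file.path(dir, "hospitals.csv"),
                      file.path(dir, "distances.csv"))
  expect_equal(back$units$population, region$units$population)
  expect_equal(back$hospitals$beds, region$hospitals$beds)
  expect_equal(back$hospitals$grade, region$hospitals$grade)
  expect_equal(back$hospitals$type, region$hospitals$type)
  ord <- function(d) d[order(d$pair_kind, d$origin_id, d$dest_id), ]
  expect_equal(ord(back$distances)$km, ord(region$distances)$km,
               tolerance = 1e-12)
})

test_that("write_results emits the decomposition schema and round-trips", {
  dir <- withr::local_tempdir()
  res <- compute_accessibility(two_township_region())
  paths <- write_results(res, dir)
  tab <- read_results(paths[["csv"]])
  expect_equal(nrow(tab), 2)
  expect_true(all(c("A", "A_p", "A_c", "A_m1", "A_m2") %in% names(tab)))
  expect_equal(tab$A, res$townships$A, tolerance = 1e-12)
  expect_true(file.exists(paths[["geojson"]]))
  gj <- jsonlite::read_json(paths[["geojson"]])
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), 2)
})

test_that("an empty result writes a header-only table", {
  dir <- withr::local_tempdir()
  res <- compute_accessibility(two_township_region())
  res$townships <- res$townships[0, ]
  paths <- write_results(res, dir)
  tab <- read_results(paths[["csv"]])
  expect_equal(nrow(tab), 0)
  expect_true("A" %in% names(tab))
})

test_that("coordinates are required when no distance table is given", {
  region <- two_township_region()
  u <- region$units; u$x_km[1] <- NA
  expect_error(
    fca_region(u[, c("unit_id", "level", "parent_id", "population",
                     "x_km", "y_km")],
               region$hospitals[, c("hospital_id", "tier", "admin_id",
                                    "beds", "grade", "type", "x_km",
                                    "y_km")]),
    "coordinates")
})
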