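# Four-stage accessibility engine.

test_that("decay is a positive, non-increasing gravity kernel", {
  expect_equal(decay(2, decay_params(exponent = 1)), 0.5)
  expect_equal(decay(0, decay_params(exponent = 1, floor = 0.1)), 10)
  expect_equal(decay(3, decay_params("gaussian", bandwidth = 3)), exp(-1))
  d <- sort(runif(50, 0, 100))
  for (p in list(decay_params(), decay_params(exponent = 2),
                 decay_params("gaussian", bandwidth = 15))) {
    w <- decay(d, p)
    expect_true(all(w > 0))
    expect_true(all(diff(w) <= 0))
  }
  expect_error(decay(-1), "non-negative")
})

test_that("supply-demand ratio handles zero supply and zero demand", {
  expect_equal(supply_demand_ratio(100, 2000), 0.05)
  expect_equal(supply_demand_ratio(50, 0), 0)
  expect_equal(supply_demand_ratio(0, 1000), 0)
  expect_error(supply_demand_ratio(-1, 10), "non-negative")
})

test_that("stage values on the minimal fixture match hand evaluation", {
  region <- minimal_fixture()
  scen <- scenario("business_as_usual")
  res <- compute_accessibility(region, scen)
  t <- res$townships

  # stage 1: 12 beds / 10000 residents, distance at the 0.1 km floor
  expect_equal(t$A_p, (12 / 10000) * 10, tolerance = 1e-12)
  # stage 2: R_c = 100 / (0.43 * 10000); d_pc = 10 km
  expect_equal(t$A_c, 100 / (0.43 * 10000) / 10, tolerance = 1e-12)
  # stage 3: R_m = 500 / ((0.1 + 0.43*0.63) * 10000); d_pm = 30 km
  r_m <- 500 / ((0.1 + 0.43 * 0.63) * 10000)
  expect_equal(t$A_m1, r_m / 30, tolerance = 1e-12)
  # stage 4: same pooled ratio along the county->municipal edge, 20 km
  expect_equal(t$A_m2, r_m / 20, tolerance = 1e-12)
  expect_equal(t$A, t$A_p + t$A_c + t$A_m1 + t$A_m2, tolerance = 1e-14)

  # referred pools
  ref <- res$referred
  expect_equal(ref$referred_population[ref$level == "county"], 4300)
  expect_equal(ref$referred_population[ref$level == "city"],
               (0.1 + 0.43 * 0.63) * 10000)
})

test_that("referred municipal demand pools follow beta + alpha*gamma", {
  region <- minimal_fixture()
  scen <- scenario("business_as_usual", alpha = 0.5, beta = 0.1, gamma = 0.6)
  res <- compute_accessibility(region, scen)
  ref <- res$referred
  expect_equal(ref$referred_population[ref$level == "city"], 0.4 * 10000)
})

test_that("zero referral flow collapses the decomposition to A_p", {
  region <- two_township_region()
  res <- compute_accessibility(
    region, scenario("business_as_usual", alpha = 0, beta = 0, gamma = 0))
  expect_true(all(res$townships$A_c == 0))
  expect_true(all(res$townships$A_m1 == 0))
  expect_true(all(res$townships$A_m2 == 0))
  expect_equal(res$townships$A, res$townships$A_p)

  # county route closed (gamma = 0) kills A_m2 but not direct A_m1
  res2 <- compute_accessibility(
    region, scenario("business_as_usual", alpha = 0.4, beta = 0.1,
                     gamma = 0))
  expect_true(all(res2$townships$A_m2 == 0))
  expect_true(all(res2$townships$A_m1 > 0))

  # alpha = 0 closes both the county tier and the county->municipal route
  res3 <- compute_accessibility(
    region, scenario("business_as_usual", alpha = 0, beta = 0.1,
                     gamma = 0.6))
  expect_true(all(res3$townships$A_c == 0))
  expect_true(all(res3$townships$A_m2 == 0))
})

test_that("townships without a primary institution have no entry point", {
  units <- tibble::tibble(
    unit_id = c("c1", "k1", "t1", "t2"),
    level = c("city", "county", "township", "township"),
    parent_id = c(NA, "c1", "k1", "k1"),
    population = c(0, 0, 10000, 5000),
    x_km = c(0, 0, 0, 5), y_km = 0
  )
  hospitals <- tibble::tibble(
    hospital_id = c("p1", "h1", "m1"),
    tier = c("primary", "county", "municipal"),
    admin_id = c("t1", "k1", "c1"),
    beds = c(15, 100, 400),
    grade = "secondary", type = "general",
    x_km = c(1, 2, 3), y_km = 0
  )
  expect_warning(region <- fca_region(units, hospitals),
                 "no primary institution")
  res <- compute_accessibility(region)
  t2 <- res$townships[res$townships$unit_id == "t2", ]
  expect_equal(t2$A, 0)
  t1 <- res$townships[res$townships$unit_id == "t1", ]
  expect_true(t1$A > 0)
})

test_that("equidistant identical primaries split stage-1 access equally", {
  units <- tibble::tibble(
    unit_id = c("c1", "k1", "t1"),
    level = c("city", "county", "township"),
    parent_id = c(NA, "c1", "k1"),
    population = c(0, 0, 10000),
    x_km = 0, y_km = 0
  )
  hospitals <- tibble::tibble(
    hospital_id = c("p1", "p2", "h1", "m1"),
    tier = c("primary", "primary", "county", "municipal"),
    admin_id = c("t1", "t1", "k1", "c1"),
    beds = c(10, 10, 100, 400),
    grade = c("secondary", "secondary", "secondary", "tertiary"),
    type = "general",
    x_km = c(2, -2, 5, 8), y_km = 0
  )
  region <- fca_region(units, hospitals, detour = 1)
  w <- hierfca:::edge_selection_weights(region, "ip", weight_tables())
  expect_equal(w$g, c(0.5, 0.5))
  res <- compute_accessibility(region)
  # pooled ratio 20/10000 decayed over 2 km, weights 0.5 each
  expect_equal(res$townships$A_p, (20 / 10000) / 2, tolerance = 1e-12)
})

test_that("decomposition conservation holds on generated regions", {
  for (seed in c(3, 11)) {
    region <- generate_region(region_config(seed = seed))
    res <- compute_accessibility(region, scenario("general_event"))
    t <- res$townships
    expect_equal(t$A, t$A_p + t$A_c + t$A_m1 + t$A_m2, tolerance = 1e-12)
    expect_true(all(t[, c("A_p", "A_c", "A_m1", "A_m2")] >= 0))
  }
})

test_that("scaling populations by c scales accessibility by 1/c", {
  region <- two_township_region()
  scen <- scenario("business_as_usual")
  base <- compute_accessibility(region, scen)$townships$A
  for (c_fac in c(0.5, 3)) {
    scaled <- region
    scaled$units$population <- scaled$units$population * c_fac
    a <- compute_accessibility(scaled, scen)$townships$A
    expect_equal(a, base / c_fac, tolerance = 1e-12)
  }
})

test_that("scaling beds by c scales accessibility by c", {
  region <- two_township_region()
  scen <- scenario("business_as_usual")
  base <- compute_accessibility(region, scen)$townships$A
  scaled <- region
  scaled$hospitals$beds <- scaled$hospitals$beds * 2.5
  a <- compute_accessibility(scaled, scen)$townships$A
  expect_equal(a, base * 2.5, tolerance = 1e-12)
})

test_that("higher referral rates dilute every referral-fed component", {
  region <- generate_region(region_config(seed = 5))
  lo <- compute_accessibility(
    region, scenario("business_as_usual", alpha = 0.3, gamma = 0.5))
  hi <- compute_accessibility(
    region, scenario("business_as_usual", alpha = 0.6, gamma = 0.8))
  expect_true(all(hi$townships$A_c <= lo$townships$A_c))
  expect_true(all(hi$townships$A_m1 <= lo$townships$A_m1))
  expect_true(all(hi$townships$A_m2 <= lo$townships$A_m2))
  expect_equal(hi$townships$A_p, lo$townships$A_p)
  # Eq linearity: doubling alpha halves the county component
  expect_equal(hi$townships$A_c, lo$townships$A_c / 2, tolerance = 1e-12)
})

test_that("hospital row order does not change the result", {
  region <- generate_region(region_config(seed = 9))
  res1 <- compute_accessibility(region)
  shuffled <- region
  set.seed(1)
  shuffled$hospitals <- shuffled$hospitals[sample(nrow(shuffled$hospitals)), ]
  shuffled$distances <- shuffled$distances[sample(nrow(shuffled$distances)), ]
  res2 <- compute_accessibility(shuffled)
  expect_equal(res1$townships$A, res2$townships$A, tolerance = 1e-12)
})

test_that("pipeline matches the brute-force oracle on the minimal fixture", {
  region <- minimal_fixture()
  for (scen in list(scenario("business_as_usual"),
                    scenario("major_event"),
                    scenario("business_as_usual", alpha = 0.2, beta = 0,
                             gamma = 0.9))) {
    got <- compute_accessibility(region, scen)$townships
    want <- oracle_accessibility(region, scen)
    expect_equal(got$A_p, want$A_p, tolerance = 1e-12)
    expect_equal(got$A_c, want$A_c, tolerance = 1e-12)
    expect_equal(got$A_m1, want$A_m1, tolerance = 1e-12)
    expect_equal(got$A_m2, want$A_m2, tolerance = 1e-12)
  }
})

test_that("gaussian decay feeds through identically to the oracle", {
  region <- two_township_region()
  dk <- decay_params("gaussian", bandwidth = 12)
  got <- compute_accessibility(region, scenario("general_event"),
                               decay_cfg = dk)$townships
  want <- oracle_accessibility(region, scenario("general_event"),
                               decay_cfg = dk)
  expect_equal(got$A, want$A, tolerance = 1e-12)
})
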