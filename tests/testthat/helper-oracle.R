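# Independent brute-force reference implementation of the four-stage
# accessibility model: explicit loops straight from the stage equations,
# sharing no code with the package's vectorised pipeline. Used to pin the
# pipeline down to 1e-12 on small regions.

oracle_accessibility <- function(region, scen,
                                 decay_cfg = decay_params(),
                                 tables = weight_tables()) {
  units <- as.data.frame(region$units)
  hosp <- as.data.frame(region$hospitals)
  dist <- as.data.frame(region$distances)

  dget <- function(kind, o, d) {
    km <- dist$km[dist$pair_kind == kind & dist$origin_id == o &
                    dist$dest_id == d]
    stopifnot(length(km) == 1)
    km
  }
  f <- function(d) {
    if (decay_cfg$form == "power") {
      max(d, decay_cfg$floor)^(-decay_cfg$exponent)
    } else {
      exp(-d^2 / decay_cfg$bandwidth^2)
    }
  }
  minmax <- function(v) {
    if (max(v) == min(v)) rep(0.5, length(v)) else (v - min(v)) / (max(v) - min(v))
  }

  # composite attractiveness, standardized within each tier pool
  t_score <- setNames(rep(NA_real_, nrow(hosp)), hosp$hospital_id)
  for (tier in c("primary", "county", "municipal")) {
    idx <- which(hosp$tier == tier)
    if (length(idx) == 0) next
    x1 <- unname(tables$grade_coefficients[hosp$grade[idx]])
    x2 <- hosp$beds[idx]
    x3 <- unname(tables$type_weights[hosp$type[idx]])
    t_score[idx] <- minmax(x1) + minmax(x2) + x3
  }
  g_over <- function(ids) {
    ts <- t_score[ids]
    ts / sum(ts)
  }

  town <- units[units$level == "township", ]
  pop_of_county <- function(k) sum(town$population[town$county_id == k])
  pop_of_city <- function(m) sum(town$population[town$city_id == m])

  sdr <- function(s, p) if (p > 0) s / p else 0

  out <- data.frame(unit_id = town$unit_id, A_p = 0, A_c = 0,
                    A_m1 = 0, A_m2 = 0)
  for (i in seq_len(nrow(town))) {
    ti <- town$unit_id[i]
    county <- town$county_id[i]
    city <- town$city_id[i]
    prims <- hosp[hosp$tier == "primary" & hosp$admin_id == ti, ]
    if (nrow(prims) == 0) next
    g_ip <- g_over(prims$hospital_id)

    r_p <- sdr(sum(prims$beds), town$population[i])
    p_k1 <- scen$alpha * pop_of_county(county)
    p_k2 <- (scen$beta + scen$alpha * scen$gamma) * pop_of_city(city)
    cntys <- hosp[hosp$tier == "county" & hosp$admin_id == county, ]
    munis <- hosp[hosp$tier == "municipal" & hosp$admin_id == city, ]
    r_c <- sdr(sum(cntys$beds), p_k1)
    r_m <- sdr(sum(munis$beds), p_k2)

    a_p <- 0; a_c <- 0; a_m1 <- 0; a_m2 <- 0
    for (pi in seq_len(nrow(prims))) {
      p_id <- prims$hospital_id[pi]
      a_p <- a_p + r_p * f(dget("ip", ti, p_id)) * g_ip[pi]

      if (nrow(cntys) > 0) {
        g_pc <- g_over(cntys$hospital_id)
        for (ci in seq_len(nrow(cntys))) {
          c_id <- cntys$hospital_id[ci]
          a_c <- a_c + g_ip[pi] * r_c * f(dget("pc", p_id, c_id)) * g_pc[ci]
          if (nrow(munis) > 0 && scen$alpha > 0 && scen$gamma > 0) {
            g_cm <- g_over(munis$hospital_id)
            for (mi in seq_len(nrow(munis))) {
              m_id <- munis$hospital_id[mi]
              a_m2 <- a_m2 + g_ip[pi] * g_pc[ci] * r_m *
                f(dget("cm", c_id, m_id)) * g_cm[mi]
            }
          }
        }
      }
      if (nrow(munis) > 0) {
        g_pm <- g_over(munis$hospital_id)
        for (mi in seq_len(nrow(munis))) {
          m_id <- munis$hospital_id[mi]
          a_m1 <- a_m1 + g_ip[pi] * r_m * f(dget("pm", p_id, m_id)) * g_pm[mi]
        }
      }
    }
    out$A_p[i] <- a_p; out$A_c[i] <- a_c
    out$A_m1[i] <- a_m1; out$A_m2[i] <- a_m2
  }
  out$A <- out$A_p + out$A_c + out$A_m1 + out$A_m2
  out
}

# Small random region (<= 3 townships, <= 2 hospitals per tier unit) built
# directly from tibbles, independent of the package generator.
random_micro_region <- function(seed) {
  set.seed(seed)
  n_town <- sample(1:3, 1)
  units <- tibble::tibble(
    unit_id = c("C", "K", sprintf("T%d", seq_len(n_town))),
    level = c("city", "county", rep("township", n_town)),
    parent_id = c(NA, "C", rep("K", n_town)),
    population = c(0, 0, round(runif(n_town, 2000, 50000))),
    x_km = runif(2 + n_town, 0, 50),
    y_km = runif(2 + n_town, 0, 50)
  )
  grades <- names(hierfca::weight_tables()$grade_coefficients)
  types <- names(hierfca::weight_tables()$type_weights)
  mk <- function(host_ids, tier, beds_lo, beds_hi) {
    rows <- lapply(host_ids, function(h) {
      n <- sample(0:2, 1)
      if (tier != "primary") n <- max(n, 1)
      if (n == 0) return(NULL)
      tibble::tibble(
        hospital_id = sprintf("%s_%s%d", h, tier, seq_len(n)),
        tier = tier, admin_id = h,
        beds = round(runif(n, beds_lo, beds_hi)),
        grade = sample(grades, n, replace = TRUE),
        type = sample(types, n, replace = TRUE),
        x_km = runif(n, 0, 50), y_km = runif(n, 0, 50))
    })
    dplyr::bind_rows(rows)
  }
  hospitals <- dplyr::bind_rows(
    mk(sprintf("T%d", seq_len(n_town)), "primary", 5, 30),
    mk("K", "county", 50, 500),
    mk("C", "municipal", 300, 2000)
  )
  suppressWarnings(fca_region(units, hospitals, detour = 1.3))
}

random_scenario <- function(seed) {
  set.seed(seed + 10000)
  alpha <- runif(1, 0.2, 0.8)
  scenario("business_as_usual",
           alpha = alpha,
           beta = runif(1, 0, min(0.3, 1 - alpha)),
           gamma = runif(1, 0.3, 0.9))
}
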