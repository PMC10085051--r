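# Small deterministic fixtures shared across test files.

# 1 city / 1 county / 2 townships, coordinates only (distances computed)
two_township_region <- function(detour = 1.3) {
  units <- tibble::tibble(
    unit_id = c("c1", "k1", "t1", "t2"),
    level = c("city", "county", "township", "township"),
    parent_id = c(NA, "c1", "k1", "k1"),
    population = c(0, 0, 12000, 8000),
    x_km = c(0, 0, 0, 10),
    y_km = c(0, 0, 0, 0)
  )
  hospitals <- tibble::tibble(
    hospital_id = c("p1", "p2", "k1h", "m1"),
    tier = c("primary", "primary", "county", "municipal"),
    admin_id = c("t1", "t2", "k1", "c1"),
    beds = c(10, 20, 150, 800),
    grade = c("under_secondary", "secondary", "grade_a_secondary",
              "grade_a_tertiary"),
    type = c("general", "tcm", "general", "general"),
    x_km = c(1, 11, 5, 20),
    y_km = c(0, 0, 3, 4)
  )
  fca_region(units, hospitals, detour = detour)
}
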