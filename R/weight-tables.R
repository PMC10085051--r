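# Packaged attractiveness constants for the multi-factor selection weight.
#
# Grade coefficients follow the convention that a tertiary hospital counts
# twice a secondary one and "grade-A" status adds 0.5. Type weights are
# national visit shares: the annual diagnosis-and-treatment population of
# each hospital type divided by the total across all types (2019 national
# health statistics). The six printed shares sum to 0.9999 and are used
# as published, without renormalisation.

.grade_coefficients <- c(
  under_secondary   = 0.5,
  secondary         = 1.0,
  grade_a_secondary = 1.5,
  tertiary          = 2.0,
  grade_a_tertiary  = 2.5
)

.type_weights <- c(
  general     = 0.6694,
  tcm         = 0.1418,
  icwm        = 0.0176,
  national    = 0.0036,
  specialized = 0.0919,
  mch         = 0.0756
)

.hospital_tiers <- c("primary", "county", "municipal")
.unit_levels <- c("township", "county", "city")

# tier of hospital <-> level of the administrative unit that hosts it
.tier_level <- c(primary = "township", county = "county", municipal = "city")

#' Grade coefficient of a hospital grade
#'
#' Maps an accreditation grade to its attractiveness coefficient. The scale
#' runs from 0.5 (below secondary) to 2.5 (grade-A tertiary) in steps of 0.5:
#' a tertiary hospital is weighted twice a secondary one and grade-A status
#' adds 0.5.
#'
#' @param grade Character vector of grade tokens: `"under_secondary"`,
#'   `"secondary"`, `"grade_a_secondary"`, `"tertiary"`,
#'   `"grade_a_tertiary"`.
#' @param table Named numeric vector mapping grade tokens to coefficients;
#'   defaults to the packaged scale.
#' @return Numeric vector of coefficients.
#' @export
#' @examples
#' grade_coefficient(c("secondary", "grade_a_tertiary"))
grade_coefficient <- function(grade, table = .grade_coefficients) {
  unknown <- setdiff(unique(grade), names(table))
  if (length(unknown) > 0) {
    abort(paste0("unknown hospital grade token(s): ",
                 paste(unknown, collapse = ", ")),
          class = "hierfca_vocabulary_error")
  }
  unname(table[grade])
}

#' Type selection weight of a hospital type
#'
#' Maps a hospital type to the national probability that a patient visit
#' falls on that type (share of annual diagnosis-and-treatment visits).
#' Types are general, traditional Chinese medicine (tcm), integrated
#' Chinese-Western medicine (icwm), national (ethnic-minority) medicine,
#' specialized, and maternity & child healthcare (mch).
#'
#' @param type Character vector of type tokens: `"general"`, `"tcm"`,
#'   `"icwm"`, `"national"`, `"specialized"`, `"mch"`.
#' @param table Named numeric vector mapping type tokens to probabilities;
#'   defaults to the packaged shares.
#' @return Numeric vector of selection probabilities.
#' @export
#' @examples
#' type_weight("general")
type_weight <- function(type, table = .type_weights) {
  unknown <- setdiff(unique(type), names(table))
  if (length(unknown) > 0) {
    abort(paste0("unknown hospital type token(s): ",
                 paste(unknown, collapse = ", ")),
          class = "hierfca_vocabulary_error")
  }
  unname(table[type])
}

#' Attractiveness weight configuration
#'
#' Bundles the grade-coefficient and type-weight lookup tables used when
#' building selection weights, allowing either to be overridden.
#'
#' @param grade_coefficients Named numeric vector over the five grade tokens.
#' @param type_weights Named numeric vector over the six type tokens, all in
#'   (0, 1).
#' @return A list of class `fca_weight_tables`.
#' @export
weight_tables <- function(grade_coefficients = .grade_coefficients,
                          type_weights = .type_weights) {
  if (!all(names(.grade_coefficients) %in% names(grade_coefficients))) {
    abort("grade_coefficients must cover all five grade tokens")
  }
  if (!all(names(.type_weights) %in% names(type_weights))) {
    abort("type_weights must cover all six type tokens")
  }
  if (any(!is.finite(grade_coefficients)) ||
      any(!is.finite(type_weights)) ||
      any(type_weights <= 0) || any(type_weights >= 1)) {
    abort("weight tables must be finite, with type weights in (0, 1)")
  }
  structure(list(grade_coefficients = grade_coefficients,
                 type_weights = type_weights),
            class = "fca_weight_tables")
}
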