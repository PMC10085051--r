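# Multi-factor comprehensive selection weights. Each hospital's
# attractiveness T combines a standardized grade coefficient, a standardized
# scale (bed count), and the raw type-visit probability; a demand point's
# weight over a candidate set is T normalised to sum to one. Grade and scale
# are min-max standardized over a pool of same-tier hospitals spanning the
# whole study region, so a hospital's score does not depend on who is asking.

#' Min-max standardization to [0, 1]
#'
#' Rescales a numeric vector linearly so its minimum maps to 0 and its
#' maximum to 1. A constant vector maps to 0.5 everywhere, keeping composite
#' scores comparable when a pool has no spread.
#'
#' @param values Non-empty numeric vector of finite values.
#' @return Numeric vector in `[0, 1]`.
#' @export
#' @examples
#' standardize(c(0.5, 1.5, 2.5))
standardize <- function(values) {
  if (length(values) == 0) {
    abort("cannot standardize an empty vector")
  }
  if (any(!is.finite(values))) {
    abort("cannot standardize non-finite values")
  }
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(rep(0.5, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Composite attractiveness scores for candidate hospitals
#'
#' Computes, for each candidate hospital, the composite score
#' `T = X1* + X2* + X3` where `X1*` is the min-max standardized grade
#' coefficient, `X2*` the min-max standardized bed count, and `X3` the raw
#' type-visit probability. Standardization runs over `pool` (typically all
#' same-tier hospitals in the study region), of which the candidates must be
#' a subset.
#'
#' @param candidates Hospital tibble (rows of an [fca_region]'s `hospitals`)
#'   for the demand point's candidate set; may be empty.
#' @param pool Hospital tibble over which grade and beds are standardized;
#'   must contain all candidates.
#' @param tables An [weight_tables()] configuration.
#' @return A tibble with one row per candidate: `hospital_id`, `x1_raw`,
#'   `x2_raw`, `x3`, `x1_std`, `x2_std`, `t_score`.
#' @export
composite_scores <- function(candidates, pool, tables = weight_tables()) {
  if (nrow(pool) == 0) {
    abort("standardization pool must be non-empty")
  }
  if (!all(candidates$hospital_id %in% pool$hospital_id)) {
    abort("candidates must be a subset of the standardization pool")
  }
  x1_pool <- grade_coefficient(pool$grade, tables$grade_coefficients)
  x2_pool <- as.numeric(pool$beds)
  x1_std_pool <- standardize(x1_pool)
  x2_std_pool <- standardize(x2_pool)
  idx <- match(candidates$hospital_id, pool$hospital_id)
  tibble::tibble(
    hospital_id = candidates$hospital_id,
    x1_raw = x1_pool[idx],
    x2_raw = x2_pool[idx],
    x3 = type_weight(candidates$type, tables$type_weights),
    x1_std = x1_std_pool[idx],
    x2_std = x2_std_pool[idx],
    t_score = x1_std_pool[idx] + x2_std_pool[idx] +
      type_weight(candidates$type, tables$type_weights)
  )
}

#' Selection weights of a demand point over its candidate hospitals
#'
#' Normalizes the composite scores of the candidate set so the weights sum
#' to one: `G_j = T_j / sum(T_k)`. Returns an empty tibble for an empty
#' candidate set.
#'
#' @param demand_id Identifier of the demand point (kept in the output).
#' @inheritParams composite_scores
#' @return A tibble `demand_id`, `hospital_id`, `t_score`, `g`.
#' @export
selection_weights <- function(demand_id, candidates, pool,
                              tables = weight_tables()) {
  scores <- composite_scores(candidates, pool, tables)
  if (nrow(scores) == 0) {
    return(tibble::tibble(demand_id = character(), hospital_id = character(),
                          t_score = double(), g = double()))
  }
  total <- sum(scores$t_score)
  if (total <= 0) {
    abort("all composite scores are zero; selection weights undefined")
  }
  tibble::tibble(
    demand_id = demand_id,
    hospital_id = scores$hospital_id,
    t_score = scores$t_score,
    g = scores$t_score / total
  )
}

# Selection weights for every within-catchment edge of one pair kind.
# Standardization pools are the destination tier's hospitals across the
# whole region; normalisation is per origin over its catchment candidates.
edge_selection_weights <- function(region, pair_kind, tables) {
  dest_tier <- c(ip = "primary", pc = "county", pm = "municipal",
                 cm = "municipal")[[pair_kind]]
  pool <- region$hospitals[region$hospitals$tier == dest_tier, ]
  edges <- region$distances[region$distances$pair_kind == pair_kind, ]
  if (nrow(edges) == 0) {
    return(tibble::tibble(origin_id = character(), dest_id = character(),
                          km = double(), t_score = double(), g = double()))
  }
  scores <- composite_scores(
    pool[match(edges$dest_id, pool$hospital_id), ], pool, tables)
  edges$t_score <- scores$t_score
  edges |>
    dplyr::group_by(.data$origin_id) |>
    dplyr::mutate(g = .data$t_score / sum(.data$t_score)) |>
    dplyr::ungroup() |>
    dplyr::select("origin_id", "dest_id", "km", "t_score", "g")
}
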