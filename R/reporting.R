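# Scenario comparison, four-class accessibility classification, and
# per-tier contribution rates.

#' Run all three packaged scenarios on one region
#'
#' Convenience wrapper computing accessibility under `business_as_usual`,
#' `general_event` and `major_event` with shared decay and weight settings.
#'
#' @inheritParams compute_accessibility
#' @param derive_rates If `TRUE`, referral rates are re-derived from the
#'   region's capacity structure via [derive_scenario_rates()]; otherwise
#'   the packaged published rates are used (default).
#' @return Named list of [compute_accessibility()] results.
#' @export
run_scenarios <- function(region, decay_cfg = decay_params(),
                          tables = weight_tables(), derive_rates = FALSE) {
  scens <- lapply(.scenario_names, function(nm) {
    if (derive_rates) derive_scenario_rates(region, nm) else scenario(nm)
  })
  names(scens) <- .scenario_names
  lapply(scens, function(s) {
    compute_accessibility(region, s, decay_cfg = decay_cfg, tables = tables)
  })
}

#' Summarize accessibility across scenarios
#'
#' Per-scenario mean and standard deviation of township accessibility
#' (unweighted across townships, population-sd convention), the
#' population-weighted mean, and the percent change of the mean against the
#' baseline scenario (`business_as_usual` when present, else the first).
#'
#' @param results Named list of [compute_accessibility()] results computed
#'   on the same region.
#' @param baseline Name of the baseline scenario.
#' @return A tibble with one row per scenario: `scenario`, `mean_A`, `sd_A`,
#'   `weighted_mean_A`, `pct_change_mean`.
#' @export
summarize_scenarios <- function(results,
                                baseline = if ("business_as_usual" %in%
                                               names(results))
                                  "business_as_usual" else names(results)[1]) {
  if (length(results) == 0 || is.null(names(results)) ||
      any(names(results) == "")) {
    abort("results must be a non-empty named list")
  }
  ids <- lapply(results, function(r) r$townships$unit_id)
  if (!all(vapply(ids, identical, logical(1), y = ids[[1]]))) {
    abort("all results must come from the same region",
          class = "hierfca_validation_error")
  }
  if (!baseline %in% names(results)) {
    abort("baseline scenario not found among the results")
  }
  tab <- purrr::map_dfr(names(results), function(nm) {
    g <- glance(results[[nm]])
    tibble::tibble(scenario = nm, mean_A = g$mean_A, sd_A = g$sd_A,
                   weighted_mean_A = g$weighted_mean_A)
  })
  base_mean <- tab$mean_A[tab$scenario == baseline]
  tab$pct_change_mean <- if (base_mean != 0) {
    100 * (tab$mean_A - base_mean) / base_mean
  } else NA_real_
  tab
}

.access_classes <- c("low", "lower", "higher", "high")

#' Classify townships into four accessibility classes
#'
#' Assigns every township to one of four ordered classes (`low`, `lower`,
#' `higher`, `high`) by quartile breaks (default) or Jenks natural breaks,
#' and reports the population share of each class per city and overall.
#' When all values coincide, every township falls in the `low` class. Jenks
#' with fewer than four distinct values falls back to quartiles with a
#' warning.
#'
#' @param result An [compute_accessibility()] result.
#' @param method `"quartile"` (default) or `"jenks"`.
#' @return A list of class `fca_classification` with `townships` (the
#'   per-township class) and `shares` (population share per class, per city
#'   and overall), plus the `method` used.
#' @export
classify_accessibility <- function(result, method = c("quartile", "jenks")) {
  stopifnot(inherits(result, "fca_accessibility"))
  method <- match.arg(method)
  tab <- result$townships
  if (nrow(tab) == 0) abort("empty accessibility result")
  a <- tab$A

  if (method == "jenks" && length(unique(a)) < 4) {
    warn("fewer than 4 distinct values; falling back to quartile breaks")
    method <- "quartile"
  }
  breaks <- switch(method,
                   quartile = unique(quantile(a, c(0.25, 0.5, 0.75))),
                   jenks = jenks_breaks(a, 4))
  cls <- cut(a, breaks = unique(c(-Inf, breaks, Inf)),
             labels = .access_classes[seq_len(length(unique(
               c(-Inf, breaks, Inf))) - 1)],
             right = TRUE)
  cls <- factor(as.character(cls), levels = .access_classes)
  cls[is.na(cls)] <- "low"

  tab$class <- cls
  shares_by <- function(d, label) {
    tot <- sum(d$population)
    share <- vapply(.access_classes, function(k) {
      if (tot > 0) sum(d$population[d$class == k]) / tot else NA_real_
    }, double(1), USE.NAMES = FALSE)
    tibble::tibble(region = label, class = .access_classes, share = share)
  }
  shares <- dplyr::bind_rows(
    shares_by(tab, "overall"),
    purrr::map_dfr(split(tab, tab$city_id),
                   function(d) shares_by(d, d$city_id[1]))
  )
  structure(list(townships = tab[, c("unit_id", "city_id", "population",
                                     "A", "class")],
                 shares = shares, method = method),
            class = "fca_classification")
}

#' @export
print.fca_classification <- function(x, ...) {
  cat(sprintf("<fca_classification> %s breaks, %d townships\n",
              x$method, nrow(x$townships)))
  print(table(x$townships$class))
  invisible(x)
}

# Fisher's optimal 1-D partition into k classes (Jenks natural breaks):
# dynamic programme minimising within-class sum of squared deviations.
jenks_breaks <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  cx <- cumsum(x)
  cx2 <- cumsum(x^2)
  ssq <- function(i, j) {
    # within-class SSD of x[i..j]
    s <- cx[j] - if (i > 1) cx[i - 1] else 0
    s2 <- cx2[j] - if (i > 1) cx2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  cost <- matrix(Inf, n, k)
  split_at <- matrix(0L, n, k)
  for (j in seq_len(n)) cost[j, 1] <- ssq(1, j)
  for (m in 2:k) {
    for (j in m:n) {
      for (i in m:j) {
        cand <- cost[i - 1, m - 1] + ssq(i, j)
        if (cand < cost[j, m]) {
          cost[j, m] <- cand
          split_at[j, m] <- i
        }
      }
    }
  }
  cuts <- integer(k - 1)
  j <- n
  for (m in k:2) {
    i <- split_at[j, m]
    cuts[m - 1] <- i - 1L
    j <- i - 1L
  }
  x[cuts]
}

#' Per-tier contribution rates to accessibility
#'
#' For each township, the share of total accessibility contributed by the
#' primary tier, the county tier, and the municipal tier (direct plus
#' county-routed). Townships with zero total accessibility are reported
#' with missing shares. Regional aggregates (per city and overall) are
#' population-weighted: the ratio of population-weighted component sums to
#' the population-weighted total, over townships with positive access.
#'
#' @param result An [compute_accessibility()] result.
#' @return A list of class `fca_contribution` with `townships`
#'   (`share_primary`, `share_county`, `share_municipal` per township) and
#'   `regions` (weighted aggregates per city and overall).
#' @export
contribution_rates <- function(result) {
  stopifnot(inherits(result, "fca_accessibility"))
  tab <- result$townships
  pos <- tab$A > 0
  shares <- tibble::tibble(
    unit_id = tab$unit_id,
    city_id = tab$city_id,
    population = tab$population,
    share_primary = ifelse(pos, tab$A_p / tab$A, NA_real_),
    share_county = ifelse(pos, tab$A_c / tab$A, NA_real_),
    share_municipal = ifelse(pos, (tab$A_m1 + tab$A_m2) / tab$A, NA_real_)
  )
  agg <- function(d, label) {
    keep <- d$A > 0
    wt <- sum(d$population[keep] * d$A[keep])
    tibble::tibble(
      region = label,
      share_primary = if (wt > 0)
        sum(d$population[keep] * d$A_p[keep]) / wt else NA_real_,
      share_county = if (wt > 0)
        sum(d$population[keep] * d$A_c[keep]) / wt else NA_real_,
      share_municipal = if (wt > 0)
        sum(d$population[keep] * (d$A_m1[keep] + d$A_m2[keep])) / wt
      else NA_real_
    )
  }
  regions <- dplyr::bind_rows(
    agg(tab, "overall"),
    purrr::map_dfr(split(tab, tab$city_id),
                   function(d) agg(d, d$city_id[1]))
  )
  structure(list(townships = shares, regions = regions),
            class = "fca_contribution")
}

#' @export
print.fca_contribution <- function(x, ...) {
  cat("<fca_contribution>\n")
  print(x$regions)
  invisible(x)
}
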