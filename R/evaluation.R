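# Scoring enrichment output against synthetic ground truth: exact and
# group-level match rates (unique and volume-weighted) and recovery of
# per-participant purchase-profile proportions.

#' Score generic classification against ground truth
#'
#' Mirrors a manual assessment of name matching: a match is *exact* when
#' the assigned category equals the true category, and a *group* match
#' when the assigned food group equals the true group (e.g. the right kind
#' of milk versus any milk product). Unmatched products are excluded from
#' the denominators but counted. Rates are reported per unique product and
#' weighted by purchase volume.
#'
#' @param enrichment A `cpd_enrichment` object (or its match table).
#' @param truth Truth table mapping observed products to their true
#'   category/group: columns `item_number`, `item_name`, `category_id`,
#'   `group`, and a volume column (`total_quantity` or `n_lines`). The
#'   `observed_products` table of [generate_cohort()] fits directly.
#' @param generic_db Generic database (to resolve assigned categories to
#'   food groups).
#' @param sample_n Optional number of unique products to audit; sampled
#'   uniformly (or volume-weighted) with `seed`.
#' @param seed Seed for the audit sample.
#' @param volume_weighted_sample If `TRUE`, sample products with
#'   probability proportional to purchase volume.
#' @return A list of class `matching_evaluation`: `rates` (one-row
#'   tibble: `exact_rate_unique`, `exact_rate_volume`, `group_rate_unique`,
#'   `group_rate_volume`, `n_evaluated`, `n_excluded_unmatched`) and
#'   `confusion` (tibble of true group x assigned group counts). `tidy()`
#'   returns the confusion table, `glance()` the rates.
#' @export
evaluate_matching <- function(enrichment, truth, generic_db,
                              sample_n = NULL, seed = NULL,
                              volume_weighted_sample = FALSE) {
  matches <- if (inherits(enrichment, "cpd_enrichment")) {
    enrichment$matches
  } else {
    enrichment
  }
  joined <- matches |>
    dplyr::inner_join(
      truth |>
        dplyr::select("item_number", "item_name",
                      true_category = "category_id", true_group = "group",
                      dplyr::any_of(c("total_quantity", "n_lines"))),
      by = c(item_number_raw = "item_number", item_name_raw = "item_name")
    )
  if (nrow(joined) < nrow(matches)) {
    stop("ground truth is missing ", nrow(matches) - nrow(joined),
         " evaluated product(s)")
  }
  if (!is.null(sample_n) && sample_n < nrow(joined)) {
    if (!is.null(seed)) set.seed(seed)
    prob <- if (volume_weighted_sample) joined$purchase_volume else NULL
    joined <- joined[sort(sample.int(nrow(joined), sample_n, prob = prob)), ]
  }

  group_of <- setNames(generic_db$food_group, generic_db$category_id)
  joined$assigned_group <- unname(group_of[joined$category_id])

  evaluable <- !is.na(joined$category_id)
  n_excluded <- sum(!evaluable)
  ev <- joined[evaluable, ]
  vol <- ev$purchase_volume
  exact <- ev$category_id == ev$true_category
  group <- !is.na(ev$assigned_group) & ev$assigned_group == ev$true_group

  rates <- tibble::tibble(
    exact_rate_unique = mean(exact),
    exact_rate_volume = sum(vol[exact]) / sum(vol),
    group_rate_unique = mean(group | exact),
    group_rate_volume = sum(vol[group | exact]) / sum(vol),
    n_evaluated = nrow(ev),
    n_excluded_unmatched = n_excluded
  )
  confusion <- ev |>
    dplyr::count(.data$true_group, .data$assigned_group, name = "n") |>
    dplyr::arrange(.data$true_group, .data$assigned_group)
  structure(list(rates = rates, confusion = confusion),
            class = "matching_evaluation")
}

#' @export
print.matching_evaluation <- function(x, ...) {
  r <- x$rates
  cat("<matching_evaluation>\n")
  cat(sprintf("  exact matches: %.1f%% unique / %.1f%% by volume\n",
              100 * r$exact_rate_unique, 100 * r$exact_rate_volume))
  cat(sprintf("  group matches: %.1f%% unique / %.1f%% by volume\n",
              100 * r$group_rate_unique, 100 * r$group_rate_volume))
  cat(sprintf("  evaluated %d products (%d unmatched excluded)\n",
              r$n_evaluated, r$n_excluded_unmatched))
  invisible(x)
}

#' @export
tidy.matching_evaluation <- function(x, ...) x$confusion

#' @export
glance.matching_evaluation <- function(x, ...) x$rates

#' Recovery of true purchase-profile proportions
#'
#' Compares each participant's full-data group-proportion estimate with
#' the generator's true preference vector and reports the absolute error
#' together with a binomial-standard-error band at the participant's line
#' count.
#'
#' @param lines Enriched line table with a `food_group` column (true or
#'   assigned groups).
#' @param truth_preferences Truth tibble (`participant_id`, `group`,
#'   `true_proportion`), as produced by [generate_cohort()].
#' @return Tibble per participant x group: `estimated`, `true_proportion`,
#'   `abs_error`, `n_lines`, `binomial_se`.
#' @export
evaluate_proportion_recovery <- function(lines, truth_preferences) {
  est <- lines |>
    dplyr::filter(!is.na(.data$food_group)) |>
    dplyr::count(.data$participant_id, .data$food_group, name = "n") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(n_lines = sum(.data$n),
                  estimated = .data$n / .data$n_lines) |>
    dplyr::ungroup()
  truth_preferences |>
    dplyr::left_join(est, by = c("participant_id", group = "food_group")) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(n_lines = max(.data$n_lines, 0, na.rm = TRUE)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      estimated = tidyr::replace_na(.data$estimated, 0),
      abs_error = abs(.data$estimated - .data$true_proportion),
      binomial_se = sqrt(.data$true_proportion *
                           (1 - .data$true_proportion) /
                           pmax(.data$n_lines, 1))
    ) |>
    dplyr::select("participant_id", "group", "estimated",
                  "true_proportion", "abs_error", "n_lines", "binomial_se")
}
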