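# Nutrient concordance between generic (category-average) and specific
# (brand-level) databases for doubly-matched products.

#' Modified relative difference between two non-negative values
#'
#' `|a - b| / max(a, b)`, the scale-invariant concordance statistic used
#' to compare a nutrient value from the generic food database with the
#' brand-specific value for the same product. Ranges over [0, 1]: 0 means
#' the sources agree exactly, 1 means one source reports zero while the
#' other does not. By convention the difference of two zeros is 0.
#'
#' @param a,b Non-negative numeric vectors (recycled).
#' @return Numeric vector in [0, 1].
#' @examples
#' modified_relative_difference(300, 400)  # 0.25
#' @export
modified_relative_difference <- function(a, b) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop("modified_relative_difference() is defined for non-negative values")
  }
  m <- pmax(a, b)
  out <- abs(a - b) / m
  out[m == 0] <- 0
  out
}

#' Compare nutrient values for products matched to both sources
#'
#' Selects the unique products that have both an accepted generic category
#' and a GTIN record in the branded (`gs1like`) database, and computes the
#' modified relative difference per product and nutrient where both
#' sources report the nutrient.
#'
#' @param enrichment A `cpd_enrichment` object from [enrich()].
#' @param generic_db Generic database tibble.
#' @param specific_dbs Named list of specific databases; the `gs1like`
#'   entry is the branded comparator.
#' @param nutrients Character vector of nutrient columns to compare.
#' @return Tibble with one row per (product, nutrient): keys, `nutrient`,
#'   `value_generic`, `value_specific`, `rel_diff`, `purchase_volume`,
#'   `category_id`. The number of products excluded for missing either
#'   source is attached as attribute `n_excluded`.
#' @export
compare_nutrients <- function(enrichment, generic_db, specific_dbs,
                              nutrients = c("energy_kj", "fat_g",
                                            "protein_g", "carbohydrate_g")) {
  matches <- enrichment$matches
  gs1 <- specific_dbs$gs1like
  if (is.null(gs1)) stop("specific_dbs must contain a gs1like table")

  # the generic comparator is a food-composition table; custom non-food
  # categories carry no meaningful nutrient values and are not compared
  food_cats <- if ("is_food" %in% names(generic_db)) {
    generic_db$category_id[generic_db$is_food]
  } else {
    generic_db$category_id
  }
  cand <- matches |>
    dplyr::filter(!is.na(.data$category_id), !is.na(.data$gtin),
                  .data$category_id %in% food_cats,
                  .data$gtin %in% gs1$gtin)
  n_excluded <- nrow(matches) - nrow(cand)

  gen <- generic_db[, c("category_id", nutrients)] |>
    tidyr::pivot_longer(dplyr::all_of(nutrients), names_to = "nutrient",
                        values_to = "value_generic")
  spec <- gs1[, c("gtin", nutrients)] |>
    tidyr::pivot_longer(dplyr::all_of(nutrients), names_to = "nutrient",
                        values_to = "value_specific")

  out <- cand |>
    dplyr::select("item_number_raw", "item_name_raw", "gtin",
                  "category_id", "purchase_volume") |>
    dplyr::inner_join(gen, by = "category_id",
                      relationship = "many-to-many") |>
    dplyr::inner_join(spec, by = c("gtin", "nutrient")) |>
    dplyr::filter(!is.na(.data$value_generic),
                  !is.na(.data$value_specific)) |>
    dplyr::mutate(rel_diff = modified_relative_difference(
      .data$value_generic, .data$value_specific))
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Cumulative distribution of the modified relative difference
#'
#' @param comparisons Tibble from [compare_nutrients()].
#' @param nutrient Nutrient to plot; `NULL` pools all rows.
#' @param weighting `"unique"` (each product counts once) or `"volume"`
#'   (weighted by purchase volume).
#' @return Tibble (`rel_diff`, `cum_fraction`): a monotone step function
#'   reaching 1 at the largest observed difference. Zero rows are an
#'   explicit empty result.
#' @export
rel_diff_cdf <- function(comparisons, nutrient = NULL,
                         weighting = c("unique", "volume")) {
  weighting <- match.arg(weighting)
  x <- comparisons
  if (!is.null(nutrient)) x <- dplyr::filter(x, .data$nutrient == !!nutrient)
  if (nrow(x) == 0L) {
    return(tibble::tibble(rel_diff = numeric(), cum_fraction = numeric()))
  }
  w <- if (weighting == "volume") x$purchase_volume else rep(1, nrow(x))
  ord <- order(x$rel_diff)
  d <- x$rel_diff[ord]
  w <- w[ord]
  cum <- cumsum(w) / sum(w)
  keep <- !duplicated(d, fromLast = TRUE)
  tibble::tibble(rel_diff = d[keep], cum_fraction = cum[keep])
}

#' Median modified relative difference per product group
#'
#' @param comparisons Tibble from [compare_nutrients()].
#' @param generic_db Optional generic database for category names.
#' @param nutrient Nutrient to summarize (default `"energy_kj"`).
#' @return Tibble with one row per category plus an `overall` row:
#'   `category_id`, `n_products`, `median_rel_diff`.
#' @export
group_medians <- function(comparisons, generic_db = NULL,
                          nutrient = "energy_kj") {
  x <- dplyr::filter(comparisons, .data$nutrient == !!nutrient)
  per_cat <- x |>
    dplyr::group_by(.data$category_id) |>
    dplyr::summarise(n_products = dplyr::n(),
                     median_rel_diff = median(.data$rel_diff),
                     .groups = "drop") |>
    dplyr::arrange(.data$category_id)
  overall <- tibble::tibble(
    category_id = "overall",
    n_products = nrow(x),
    median_rel_diff = if (nrow(x)) median(x$rel_diff) else NA_real_
  )
  out <- dplyr::bind_rows(per_cat, overall)
  if (!is.null(generic_db)) {
    out <- dplyr::left_join(
      out, generic_db[, c("category_id", "category_name")],
      by = "category_id")
  }
  out
}
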