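# Retailer-coverage analysis: how an individual's purchase profile over
# the top food product groups distorts when only a subset of retailers
# contributes data, and how the distortion shrinks as retailers are
# cumulatively combined.

#' Rank retailers by total purchases
#'
#' @param lines Enriched line table (needs `retailer_id`).
#' @return Tibble (`retailer_id`, `n_lines`, `rank`) in descending line
#'   count with a deterministic `retailer_id` tie-break.
#' @export
rank_retailers <- function(lines) {
  lines |>
    dplyr::count(.data$retailer_id, name = "n_lines") |>
    dplyr::arrange(dplyr::desc(.data$n_lines), .data$retailer_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}

#' The K most common food product groups
#'
#' Cohort-wide line counts over food groups (`is_food` lines with a
#' non-missing `food_group`). Warns and returns all groups when fewer than
#' `k` are present.
#'
#' @param lines Enriched line table with `food_group` and `is_food`.
#' @param k Number of groups to keep (default 20).
#' @return Character vector of group names, most frequent first.
#' @export
top_food_groups <- function(lines, k = 20) {
  counts <- lines |>
    dplyr::filter(!is.na(.data$food_group),
                  is.na(.data$is_food) | .data$is_food) |>
    dplyr::count(.data$food_group, name = "n_lines") |>
    dplyr::arrange(dplyr::desc(.data$n_lines), .data$food_group)
  if (nrow(counts) < k) {
    warning("only ", nrow(counts), " food groups present; returning all")
  }
  head(counts$food_group, k)
}

# per-(participant, retailer, group) purchase weights; the workhorse that
# lets every subset analysis run off one aggregation
coverage_cells <- function(lines, groups,
                           weight = c("quantity", "lines", "spend")) {
  weight <- match.arg(weight)
  w <- switch(weight,
    quantity = as.numeric(lines$quantity),
    lines = rep(1, nrow(lines)),
    spend = as.numeric(lines$quantity * lines$unit_price_ore -
                         lines$discount_ore)
  )
  tibble::tibble(
    participant_id = lines$participant_id,
    retailer_id = lines$retailer_id,
    group = ifelse(lines$food_group %in% groups, lines$food_group,
                   NA_character_),
    w = w
  ) |>
    dplyr::group_by(.data$participant_id, .data$retailer_id, .data$group) |>
    dplyr::summarise(w = sum(.data$w), .groups = "drop")
}

#' Purchase-profile proportions for one participant under a retailer subset
#'
#' The proportion of the participant's purchases (restricted to the
#' subset's retailers) falling in each group; the denominator is all of
#' the participant's purchases within the subset, including lines outside
#' the requested groups. A participant with no purchases in the subset is
#' flagged (`zero_subset_flag`) and gets `NA` proportions.
#'
#' @param lines Enriched line table.
#' @param participant Participant id.
#' @param retailer_subset Character vector of retailer ids.
#' @param groups Character vector of group names (see
#'   [top_food_groups()]).
#' @param weight Purchase weight: `"quantity"` (lines weighted by units
#'   bought, the default), `"lines"`, or `"spend"`.
#' @return Tibble (`group`, `proportion`, `zero_subset_flag`).
#' @export
group_proportions <- function(lines, participant, retailer_subset, groups,
                              weight = c("quantity", "lines", "spend")) {
  weight <- match.arg(weight)
  unknown <- setdiff(retailer_subset, unique(lines$retailer_id))
  if (length(unknown)) {
    stop("unknown retailer id(s): ", paste(unknown, collapse = ", "))
  }
  sub <- dplyr::filter(lines, .data$participant_id == participant,
                       .data$retailer_id %in% retailer_subset)
  if (nrow(sub) == 0L) {
    return(tibble::tibble(group = groups, proportion = NA_real_,
                          zero_subset_flag = TRUE))
  }
  cells <- coverage_cells(sub, groups, weight)
  denom <- sum(cells$w)
  agg <- cells |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(w = sum(.data$w), .groups = "drop")
  tibble::tibble(
    group = groups,
    proportion = agg$w[match(groups, agg$group)] / denom,
    zero_subset_flag = FALSE
  ) |>
    dplyr::mutate(proportion = tidyr::replace_na(.data$proportion, 0))
}

default_subsets <- function(ranking, n_individual = 10) {
  ids <- ranking$retailer_id
  ind <- lapply(seq_len(min(n_individual, length(ids))),
                function(i) ids[i])
  names(ind) <- paste0("individual_", seq_along(ind))
  cum <- lapply(seq_along(ids), function(k) ids[seq_len(k)])
  names(cum) <- paste0("cumulative_", seq_along(ids))
  c(ind, cum)
}

#' Profile differences under retailer subsets, per participant
#'
#' For each participant and retailer subset, compares the subset-based
#' group-proportion profile to the all-retailer profile: the
#' percentage-point difference `100 * (p_subset - p_full)` and the
#' relative difference `100 * (p_subset - p_full) / p_full` (undefined
#' where `p_full = 0`). The default subsets are the 10 largest individual
#' retailers and every cumulative prefix of the purchase ranking.
#' Participants with no purchases in a subset are flagged and keep `NA`
#' differences; both profiles run through the identical code path, so the
#' full-set subset gives exact zeros.
#'
#' @param lines Enriched line table.
#' @param groups Group names (see [top_food_groups()]).
#' @param subsets Optional named list of retailer-id vectors; defaults to
#'   top-10 individual retailers plus all cumulative prefixes.
#' @param weight Purchase weight (see [group_proportions()]).
#' @return Tibble of class `cpd_coverage` with one row per participant x
#'   subset x group: `participant_id`, `subset_id`, `subset_type`,
#'   `subset_size`, `group`, `p_subset`, `p_full`, `pp_difference`,
#'   `rel_difference_pct`, `zero_subset_flag`.
#' @export
coverage_differences <- function(lines, groups, subsets = NULL,
                                 weight = c("quantity", "lines", "spend")) {
  weight <- match.arg(weight)
  if (is.null(subsets)) {
    subsets <- default_subsets(rank_retailers(lines))
  }
  cells <- coverage_cells(lines, groups, weight)

  profile_for <- function(cells_sub) {
    denom <- cells_sub |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(denom = sum(.data$w), .groups = "drop")
    num <- cells_sub |>
      dplyr::filter(!is.na(.data$group)) |>
      dplyr::group_by(.data$participant_id, .data$group) |>
      dplyr::summarise(w = sum(.data$w), .groups = "drop")
    tidyr::expand_grid(participant_id = unique(cells$participant_id),
                       group = groups) |>
      dplyr::left_join(num, by = c("participant_id", "group")) |>
      dplyr::left_join(denom, by = "participant_id") |>
      dplyr::mutate(proportion = ifelse(
        is.na(.data$denom), NA_real_,
        tidyr::replace_na(.data$w, 0) / .data$denom)) |>
      dplyr::select("participant_id", "group", "proportion")
  }

  full <- profile_for(cells) |>
    dplyr::rename(p_full = "proportion")

  out <- purrr::imap_dfr(subsets, function(retailers, subset_id) {
    sub_cells <- dplyr::filter(cells, .data$retailer_id %in% retailers)
    prof <- profile_for(sub_cells) |>
      dplyr::rename(p_subset = "proportion")
    dplyr::left_join(prof, full, by = c("participant_id", "group")) |>
      dplyr::mutate(
        subset_id = subset_id,
        subset_type = ifelse(grepl("^individual", subset_id),
                             "individual", "cumulative"),
        subset_size = length(retailers),
        zero_subset_flag = is.na(.data$p_subset),
        pp_difference = 100 * (.data$p_subset - .data$p_full),
        rel_difference_pct = ifelse(
          .data$p_full > 0,
          100 * (.data$p_subset - .data$p_full) / .data$p_full,
          NA_real_)
      ) |>
      dplyr::select("participant_id", "subset_id", "subset_type",
                    "subset_size", "group", "p_subset", "p_full",
                    "pp_difference", "rel_difference_pct",
                    "zero_subset_flag")
  })
  class(out) <- c("cpd_coverage", class(out))
  out
}

#' Dispersion of profile differences per subset
#'
#' Standard deviation across participants of the percentage-point
#' differences, per subset and group, plus a pooled row (all groups and
#' participants together) per subset. Zero-subset participants are
#' excluded. A single contributing participant yields `NA`.
#'
#' @param coverage A `cpd_coverage` tibble from [coverage_differences()].
#' @return Tibble (`subset_id`, `subset_type`, `subset_size`, `group`
#'   — `"(pooled)"` for the pooled rows —, `sd_pp`, `n`).
#' @export
dispersion_summary <- function(coverage) {
  ok <- dplyr::filter(coverage, !.data$zero_subset_flag)
  per_group <- ok |>
    dplyr::group_by(.data$subset_id, .data$subset_type, .data$subset_size,
                    .data$group) |>
    dplyr::summarise(sd_pp = if (dplyr::n() >= 2) sd(.data$pp_difference)
                     else NA_real_,
                     n = dplyr::n(), .groups = "drop")
  pooled <- ok |>
    dplyr::group_by(.data$subset_id, .data$subset_type,
                    .data$subset_size) |>
    dplyr::summarise(group = "(pooled)",
                     sd_pp = if (dplyr::n() >= 2) sd(.data$pp_difference)
                     else NA_real_,
                     n = dplyr::n(), .groups = "drop")
  dplyr::bind_rows(per_group, pooled) |>
    dplyr::arrange(.data$subset_type, .data$subset_size, .data$subset_id,
                   .data$group)
}

#' Percentiles of the relative profile differences per subset
#'
#' Pools the relative differences over participant x group cells (dropping
#' zero-subset participants and cells with `p_full = 0`) and reports
#' percentiles per subset. Percentile method: linear interpolation
#' (`stats::quantile` type 7).
#'
#' @param coverage A `cpd_coverage` tibble.
#' @param percentiles Percentiles to report (default 10, 50, 90).
#' @return Tibble with one row per subset: subset keys, `n_cells` and one
#'   `p<q>` column per requested percentile.
#' @export
percentile_summary <- function(coverage, percentiles = c(10, 50, 90)) {
  ok <- dplyr::filter(coverage, !.data$zero_subset_flag,
                      !is.na(.data$rel_difference_pct))
  ok |>
    dplyr::group_by(.data$subset_id, .data$subset_type,
                    .data$subset_size) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      dplyr::bind_rows(setNames(
        as.list(quantile(.data$rel_difference_pct, percentiles / 100,
                         type = 7, names = FALSE)),
        paste0("p", percentiles))),
      .groups = "drop") |>
    dplyr::arrange(.data$subset_type, .data$subset_size, .data$subset_id)
}
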