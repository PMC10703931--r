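# Cohort descriptives: per-participant purchase behaviour summarized as
# median [IQR] (min-max), whole-month inactivity, and purchase
# concentration across the product catalog.

month_index <- function(dt) {
  lt <- as.POSIXlt(dt, tz = "UTC")
  (lt$year + 1900L) * 12L + lt$mon
}

# whole calendar months from first to last receipt, inclusive
months_span <- function(first_dt, last_dt) {
  month_index(last_dt) - month_index(first_dt) + 1L
}

#' Table-style cohort summary of purchase behaviour
#'
#' Per participant: total products bought (units), average product price,
#' receipt count, receipts per month, spend per month, distinct merchants
#' used, and inactive whole months; each metric is then summarized across
#' participants as median, quartiles (linear interpolation), min and max.
#' Rate denominators use whole calendar months between the first and last
#' receipt, inclusive.
#'
#' @param purchases A purchase table.
#' @return A list of class `cohort_summary`: `per_participant` (tibble of
#'   raw per-participant metrics) and `summary` (tibble with one row per
#'   metric: `median`, `q1`, `q3`, `min`, `max`). Empty input yields empty
#'   tibbles.
#' @export
summarize_cohort <- function(purchases) {
  if (nrow(purchases) == 0L) {
    return(structure(list(per_participant = tibble::tibble(),
                          summary = tibble::tibble()),
                     class = "cohort_summary"))
  }
  receipts <- purchases |>
    dplyr::group_by(.data$participant_id, .data$retailer_id,
                    .data$purchase_datetime) |>
    dplyr::summarise(.groups = "drop")

  per_receipt <- receipts |>
    dplyr::count(.data$participant_id, name = "n_receipts")

  per_part <- purchases |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_products = sum(.data$quantity),
      spend_ore = sum(as.numeric(.data$quantity) * .data$unit_price_ore -
                        .data$discount_ore),
      n_merchants = dplyr::n_distinct(.data$retailer_id),
      first_dt = min(.data$purchase_datetime),
      last_dt = max(.data$purchase_datetime),
      .groups = "drop"
    ) |>
    dplyr::left_join(per_receipt, by = "participant_id") |>
    dplyr::mutate(
      months_on_study = months_span(.data$first_dt, .data$last_dt),
      avg_product_price_dkk = .data$spend_ore / 100 / .data$n_products,
      receipts_per_month = .data$n_receipts / .data$months_on_study,
      spend_per_month_dkk = .data$spend_ore / 100 / .data$months_on_study
    ) |>
    dplyr::left_join(inactive_months(purchases), by = "participant_id")

  metrics <- c("n_products", "avg_product_price_dkk", "n_receipts",
               "receipts_per_month", "spend_per_month_dkk", "n_merchants",
               "inactive_months")
  summary <- purrr::map_dfr(metrics, function(m) {
    v <- per_part[[m]]
    tibble::tibble(
      metric = m,
      median = median(v),
      q1 = quantile(v, 0.25, type = 7, names = FALSE),
      q3 = quantile(v, 0.75, type = 7, names = FALSE),
      min = min(v),
      max = max(v)
    )
  })
  structure(list(per_participant = per_part, summary = summary),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>  median [IQR] (min-max)\n")
  if (nrow(x$summary) == 0L) {
    cat("  (empty cohort)\n")
    return(invisible(x))
  }
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("  %-24s %.1f [%.1f-%.1f] (%.1f-%.1f)\n", s$metric,
                s$median, s$q1, s$q3, s$min, s$max))
  }
  invisible(x)
}

#' @export
tidy.cohort_summary <- function(x, ...) x$summary

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n_participants = nrow(x$per_participant))
}

#' Whole calendar months with zero purchases
#'
#' Counts months strictly inside a participant's [first receipt month,
#' last receipt month] window that contain no receipts; the boundary
#' months always contain a receipt and are never counted.
#'
#' @param purchases A purchase table.
#' @param participant Optional single participant id; the default
#'   summarizes everyone.
#' @return Tibble (`participant_id`, `inactive_months`), or a single
#'   integer when `participant` is given.
#' @export
inactive_months <- function(purchases, participant = NULL) {
  if (!is.null(participant)) {
    if (!participant %in% purchases$participant_id) {
      stop("unknown participant id: ", participant)
    }
    purchases <- dplyr::filter(purchases,
                               .data$participant_id == participant)
  }
  out <- purchases |>
    dplyr::mutate(mi = month_index(.data$purchase_datetime)) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      inactive_months = (max(.data$mi) - min(.data$mi) + 1L) -
        dplyr::n_distinct(.data$mi),
      .groups = "drop"
    )
  if (!is.null(participant)) return(out$inactive_months[1L])
  out
}

#' Purchase concentration over the most-bought products
#'
#' Fraction of all purchases accounted for by the `top_n` most frequently
#' purchased unique products (identified by the raw item number / item
#' name pair).
#'
#' @param purchases A purchase table.
#' @param top_n Number of top products (>= 1).
#' @param weight `"lines"` ranks and weights by line count; `"quantity"`
#'   by units bought.
#' @return A fraction in (0, 1].
#' @export
purchase_concentration <- function(purchases, top_n,
                                   weight = c("lines", "quantity")) {
  weight <- match.arg(weight)
  if (top_n < 1) stop("top_n must be >= 1")
  if (nrow(purchases) == 0L) stop("purchase table is empty")
  counts <- purchases |>
    dplyr::group_by(.data$item_number, .data$item_name) |>
    dplyr::summarise(w = if (weight == "lines") dplyr::n()
                     else sum(.data$quantity),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$w))
  sum(head(counts$w, top_n)) / sum(counts$w)
}
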