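# Reading and writing the pipeline's tabular interchange formats.
#
# Receipts travel as CSV or JSON-lines with one purchased line per record;
# product databases are CSV. Currency is carried in files as DKK with two
# decimals and held internally as integer ore (1/100 DKK) so that spend
# aggregates are exact and order-independent.

receipt_file_columns <- c(
  "participant_id", "retailer_id", "purchase_datetime", "item_number",
  "item_name", "unit_price_dkk", "quantity", "discount_dkk"
)

core_nutrients <- c("energy_kj", "fat_g", "protein_g", "carbohydrate_g")

dkk_to_ore <- function(x) as.integer(round(x * 100))
ore_to_dkk <- function(x) round(x / 100, 2)

parse_iso_datetime <- function(x) {
  # timezone-naive local purchase time; only calendar granularity is used
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%d"))
  out
}

format_iso_datetime <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Read receipt lines from CSV or JSON-lines
#'
#' Expects the documented flat schema: `participant_id`, `retailer_id`,
#' `purchase_datetime` (ISO-8601, timezone-naive local time),
#' `item_number`, `item_name`, `unit_price_dkk`, `quantity`,
#' `discount_dkk`. Every row is validated against the receipt-line
#' invariants (`quantity >= 1`, non-negative price and discount, discount
#' not exceeding the line total, non-empty item name); violations are
#' reported with their row number.
#'
#' @param path Path to the receipts file.
#' @param format `"csv"` or `"jsonl"`; defaults from the file extension.
#' @return A purchase table: a tibble with one row per receipt line,
#'   currency as integer ore (`unit_price_ore`, `discount_ore`) and
#'   `purchase_datetime` parsed to POSIXct. Rows keep file order.
#' @export
read_receipts <- function(path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  if (!file.exists(path)) stop("receipts file not found: ", path)
  raw <- if (format == "csv") {
    # missing columns are reported by the schema check below, not by the
    # column-spec mismatch warning
    suppressWarnings(readr::read_csv(path, col_types = readr::cols(
      participant_id = readr::col_character(),
      retailer_id = readr::col_character(),
      purchase_datetime = readr::col_character(),
      item_number = readr::col_character(),
      item_name = readr::col_character(),
      unit_price_dkk = readr::col_double(),
      quantity = readr::col_integer(),
      discount_dkk = readr::col_double()
    ), progress = FALSE))
  } else {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
    tibble::as_tibble(df)
  }
  missing_cols <- setdiff(receipt_file_columns, names(raw))
  if (length(missing_cols)) {
    stop("receipts file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[receipt_file_columns]
  as_purchase_table(raw)
}

#' Coerce a raw receipts data frame to a validated purchase table
#'
#' @param df Data frame in the file schema (DKK currency columns,
#'   character or POSIXct datetimes).
#' @return Validated tibble in the internal schema (ore currency columns).
#' @export
as_purchase_table <- function(df) {
  df <- tibble::as_tibble(df)
  out <- tibble::tibble(
    participant_id = as.character(df$participant_id),
    retailer_id = as.character(df$retailer_id),
    purchase_datetime = if (inherits(df$purchase_datetime, "POSIXct")) {
      df$purchase_datetime
    } else {
      parse_iso_datetime(as.character(df$purchase_datetime))
    },
    item_number = as.character(df$item_number),
    item_name = as.character(df$item_name),
    unit_price_ore = if ("unit_price_ore" %in% names(df)) {
      as.integer(df$unit_price_ore)
    } else {
      dkk_to_ore(as.numeric(df$unit_price_dkk))
    },
    quantity = as.integer(df$quantity),
    discount_ore = if ("discount_ore" %in% names(df)) {
      as.integer(df$discount_ore)
    } else {
      dkk_to_ore(as.numeric(df$discount_dkk))
    }
  )
  validate_purchase_table(out)
  out
}

validate_purchase_table <- function(x) {
  check_rows <- function(bad, what) {
    if (any(bad, na.rm = TRUE) || anyNA(bad)) {
      rows <- which(bad | is.na(bad))
      stop("invalid receipt line(s) [", what, "] at row(s): ",
           paste(head(rows, 5L), collapse = ", "),
           if (length(rows) > 5L) " ..." else "")
    }
  }
  check_rows(!nzchar(x$item_name) | is.na(x$item_name), "empty item_name")
  check_rows(is.na(x$quantity) | x$quantity < 1L, "quantity < 1")
  check_rows(is.na(x$unit_price_ore) | x$unit_price_ore < 0L,
             "negative unit price")
  check_rows(is.na(x$discount_ore) | x$discount_ore < 0L, "negative discount")
  check_rows(x$discount_ore > x$quantity * x$unit_price_ore,
             "discount exceeds line total")
  check_rows(is.na(x$purchase_datetime), "unparseable purchase_datetime")
  invisible(x)
}

#' Count distinct receipts in a purchase table
#'
#' A receipt is identified by the (participant, retailer, datetime) triple.
#'
#' @param purchases A purchase table.
#' @return Integer count of distinct receipts.
#' @export
count_receipts <- function(purchases) {
  if (nrow(purchases) == 0L) return(0L)
  nrow(dplyr::distinct(
    purchases, .data$participant_id, .data$retailer_id,
    .data$purchase_datetime
  ))
}

#' Read a generic (category-keyed) food database
#'
#' The generic database has one row per mutually exclusive food category
#' with per-100 g nutrient values and six regular-expression columns
#' (`pattern_brand`, `pattern_type`, `pattern_specific`, `pattern_generic`,
#' `pattern_flavor`, `pattern_fat`) used by the name-matching stage. Every
#' pattern is compiled on read; a non-compiling pattern or duplicate
#' category id is an error naming the offender.
#'
#' @param path Path to the CSV file.
#' @return Tibble of generic food records.
#' @export
read_generic_db <- function(path) {
  if (!file.exists(path)) stop("generic database file not found: ", path)
  db <- readr::read_csv(path, col_types = readr::cols(
    category_id = readr::col_character(),
    category_name = readr::col_character(),
    is_food = readr::col_logical(),
    .default = readr::col_guess()
  ), progress = FALSE)
  validate_generic_db(db)
}

pattern_columns <- c("pattern_brand", "pattern_type", "pattern_specific",
                     "pattern_generic", "pattern_flavor", "pattern_fat")

validate_generic_db <- function(db) {
  db <- tibble::as_tibble(db)
  required <- c("category_id", "category_name", "is_food",
                core_nutrients, pattern_columns)
  missing_cols <- setdiff(required, names(db))
  if (length(missing_cols)) {
    stop("generic database is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- db$category_id[duplicated(db$category_id)]
  if (length(dup)) {
    stop("duplicate category_id in generic database: ",
         paste(unique(dup), collapse = ", "))
  }
  for (col in pattern_columns) {
    db[[col]][is.na(db[[col]])] <- ""
    for (i in seq_len(nrow(db))) {
      pat <- db[[col]][i]
      if (nzchar(pat)) {
        ok <- tryCatch({grepl(pat, "x", perl = TRUE); TRUE},
                       error = function(e) FALSE,
                       warning = function(w) FALSE)
        if (!ok) {
          stop("regex in column ", col, " does not compile for category_id ",
               db$category_id[i])
        }
      }
    }
  }
  for (nut in core_nutrients) {
    if (any(db[[nut]] < 0, na.rm = TRUE)) {
      stop("negative nutrient values in column ", nut)
    }
  }
  db
}

#' Read a specific (GTIN-keyed) product database
#'
#' @param path Path to the CSV file (columns `gtin`, `product_name`,
#'   nutrient columns per 100 g, `ingredients` as a `;`-joined list,
#'   optional `risk_score` in A/B/C).
#' @param source_db One of `"gs1like"`, `"chemlike"`, `"offlike"` — which
#'   schema the table follows. Risk scores are only meaningful for
#'   `"chemlike"` records.
#' @return Tibble with gtins normalized through [normalize_item_number()];
#'   records whose check digit fails are kept and flagged via
#'   `gtin_valid = FALSE`, never silently dropped.
#' @export
read_specific_db <- function(path, source_db = c("gs1like", "chemlike",
                                                 "offlike")) {
  source_db <- match.arg(source_db)
  if (!file.exists(path)) stop("specific database file not found: ", path)
  db <- readr::read_csv(path, col_types = readr::cols(
    gtin = readr::col_character(),
    product_name = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  if (!"gtin" %in% names(db)) stop("specific database is missing column: gtin")
  norm <- normalize_item_number(db$gtin)
  db$gtin_valid <- norm$status == "gtin"
  db$gtin <- ifelse(db$gtin_valid, norm$gtin, norm$digits)
  db$source_db <- source_db
  if (source_db != "chemlike" && "risk_score" %in% names(db)) {
    db$risk_score <- NA_character_
  }
  tibble::as_tibble(db)
}

#' Write a result table to CSV or JSON-lines
#'
#' Purchase tables are written back in the file schema (DKK with two
#' decimals, ISO-8601 datetimes) so that a write/read round trip recovers
#' identical values.
#'
#' @param x A tibble or data frame.
#' @param path Output path.
#' @param format `"csv"` or `"jsonl"`; defaults from the file extension.
#' @return Invisibly, the path written.
#' @export
write_table <- function(x, path, format = c("auto", "csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.jsonl$", path)) "jsonl" else "csv"
  }
  x <- tibble::as_tibble(x)
  if (all(c("unit_price_ore", "discount_ore") %in% names(x))) {
    x <- dplyr::mutate(
      x,
      unit_price_dkk = ore_to_dkk(.data$unit_price_ore),
      discount_dkk = ore_to_dkk(.data$discount_ore),
      item_number = .data$item_number,
      purchase_datetime = format_iso_datetime(.data$purchase_datetime)
    )
    x <- x[receipt_file_columns]
  } else if ("purchase_datetime" %in% names(x) &&
             inherits(x$purchase_datetime, "POSIXct")) {
    x$purchase_datetime <- format_iso_datetime(x$purchase_datetime)
  }
  if (format == "csv") {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(x), con, verbose = FALSE)
  }
  invisible(path)
}
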