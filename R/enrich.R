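# Product enrichment: item-number filtering, GTIN-cascade matching to
# specific databases, receipt-name preprocessing with attribute
# extraction, regex scoring against the generic database, and QC flags.

#' Enrichment configuration: scoring weights, thresholds, name cleaning
#'
#' The name-matching score for a candidate category is a weighted sum of
#' regex-column hits evaluated on the cleaned, space-joined token string:
#' `w_type * [pattern_type] + w_specific * [pattern_specific] +
#' w_generic * [pattern_generic] + w_brand * [pattern_brand] +
#' w_flavor * [pattern_flavor] + w_fat * [pattern_fat]`. The best candidate
#' is accepted when its score reaches `min_score` and beats the runner-up
#' by at least `min_margin`; a win by less than `min_margin` is accepted
#' with an `ambiguous` flag and a win carried by broad descriptor evidence
#' alone (`pattern_generic` only) is flagged `greedy`. Both flag classes
#' feed the manual-review queue.
#'
#' @param weights Named numeric vector of hit weights (`type`, `specific`,
#'   `generic`, `brand`, `flavor`, `fat`).
#' @param min_score Minimum winning score for acceptance.
#' @param min_margin Minimum winner-minus-runner-up margin for a clean
#'   (non-ambiguous) acceptance.
#' @param stopwords Character vector of tokens dropped during cleaning.
#' @param abbreviations Named character vector mapping receipt
#'   abbreviations to their expansions (applied token-wise).
#' @return A list of class `enrich_config`.
#' @export
enrich_config <- function(weights = c(type = 4, specific = 3, generic = 1,
                                      brand = 2, flavor = 1, fat = 1),
                          min_score = 4,
                          min_margin = 1,
                          stopwords = c("tilbud", "kampagne", "x2"),
                          abbreviations = c(mlk = "milk", brd = "bread",
                                            chkn = "chicken")) {
  need <- c("type", "specific", "generic", "brand", "flavor", "fat")
  if (!all(need %in% names(weights))) {
    stop("weights must name all of: ", paste(need, collapse = ", "))
  }
  structure(list(
    weights = weights[need],
    min_score = as.numeric(min_score),
    min_margin = as.numeric(min_margin),
    stopwords = as.character(stopwords),
    abbreviations = abbreviations
  ), class = "enrich_config")
}

unit_regexes <- list(
  pack = "\\b(\\d+)[- ]?(pack|pak|pk|stk)\\b",
  weight = "\\b(\\d+(?:[.,]\\d+)?)\\s?(g|kg)\\b",
  volume = "\\b(\\d+(?:[.,]\\d+)?)\\s?(ml|cl|l)\\b"
)
organic_regex <- "\\b(øko|økologisk|oko|eko|org|organic)\\b"
origin_words <- c("dansk", "danish", "spansk", "spanish", "italiensk",
                  "italian", "fransk", "french")

first_capture <- function(x, pattern, group = 1L) {
  m <- regexec(pattern, x, perl = TRUE)
  vapply(seq_along(x), function(i) {
    r <- regmatches(x[i], m[i])[[1]]
    if (length(r) > group) r[group + 1L] else NA_character_
  }, character(1))
}

#' Clean receipt item names and extract structured attributes
#'
#' Lower-cases the name, parses and removes unit expressions (weight,
#' volume, pack count), organic and origin markers, expands configured
#' abbreviations and drops stopwords. Token order is preserved. The
#' cleaned, space-joined token string is the input to the regex scoring
#' stage; the extracted attributes are kept on the match result.
#'
#' @param item_names Character vector of raw receipt names.
#' @param config An [enrich_config()].
#' @return A tibble with one row per input name: `item_name_raw`,
#'   `clean_name` (space-joined tokens; may be empty), `weight_g`,
#'   `volume_ml`, `pack_count`, `organic`, `origin`.
#' @examples
#' preprocess_name("apples 6-pack")
#' @export
preprocess_name <- function(item_names, config = enrich_config()) {
  x <- stringr::str_to_lower(item_names)

  pack <- suppressWarnings(as.integer(first_capture(x, unit_regexes$pack)))
  x <- stringr::str_replace_all(x, stringr::regex(unit_regexes$pack), " ")

  w_num <- suppressWarnings(as.numeric(
    gsub(",", ".", first_capture(x, unit_regexes$weight, 1L), fixed = TRUE)))
  w_unit <- first_capture(x, unit_regexes$weight, 2L)
  weight_g <- ifelse(!is.na(w_unit) & w_unit == "kg", w_num * 1000, w_num)
  x <- stringr::str_replace_all(x, stringr::regex(unit_regexes$weight), " ")

  v_num <- suppressWarnings(as.numeric(
    gsub(",", ".", first_capture(x, unit_regexes$volume, 1L), fixed = TRUE)))
  v_unit <- first_capture(x, unit_regexes$volume, 2L)
  volume_ml <- dplyr::case_when(
    is.na(v_unit) ~ NA_real_,
    v_unit == "l" ~ v_num * 1000,
    v_unit == "cl" ~ v_num * 10,
    TRUE ~ v_num
  )
  x <- stringr::str_replace_all(x, stringr::regex(unit_regexes$volume), " ")

  organic <- stringr::str_detect(x, stringr::regex(organic_regex))
  x <- stringr::str_replace_all(x, stringr::regex(organic_regex), " ")

  origin_pat <- paste0("\\b(", paste(origin_words, collapse = "|"), ")\\b")
  origin <- first_capture(x, origin_pat)
  x <- stringr::str_replace_all(x, stringr::regex(origin_pat), " ")

  # tokenize, expand abbreviations, drop stopwords and bare numbers
  toks <- stringr::str_split(stringr::str_squish(
    stringr::str_replace_all(x, "[^[:alnum:]æøå-]", " ")), " ")
  abb <- config$abbreviations
  sw <- config$stopwords
  clean <- vapply(toks, function(tt) {
    tt <- tt[nzchar(tt)]
    if (length(abb)) {
      hit <- match(tt, names(abb))
      tt[!is.na(hit)] <- abb[hit[!is.na(hit)]]
    }
    tt <- tt[!(tt %in% sw) & !grepl("^[0-9]+$", tt)]
    paste(tt, collapse = " ")
  }, character(1))

  tibble::tibble(
    item_name_raw = item_names,
    clean_name = clean,
    weight_g = weight_g,
    volume_ml = volume_ml,
    pack_count = pack,
    organic = organic,
    origin = origin
  )
}

# Evaluate the six pattern columns of every category against a vector of
# cleaned names. Returns, per name, the best and runner-up score, the best
# category, and whether the best category's score came from pattern_generic
# evidence alone.
score_names_against_db <- function(clean_names, generic_db, config) {
  w <- config$weights
  n <- length(clean_names)
  nc <- nrow(generic_db)
  cols <- c(type = "pattern_type", specific = "pattern_specific",
            generic = "pattern_generic", brand = "pattern_brand",
            flavor = "pattern_flavor", fat = "pattern_fat")

  best_score <- numeric(n)
  best_cat <- rep(NA_character_, n)
  best_generic_only <- rep(FALSE, n)
  second_score <- numeric(n)

  # category order = lexicographic category_id, so that "first strictly
  # greater score wins" realizes the deterministic tie-break
  ord <- order(generic_db$category_id, method = "radix")
  for (ci in ord) {
    score <- numeric(n)
    nongeneric_hit <- rep(FALSE, n)
    for (k in names(cols)) {
      pat <- generic_db[[cols[[k]]]][ci]
      if (is.na(pat) || !nzchar(pat)) next
      hit <- stringr::str_detect(clean_names, stringr::regex(pat))
      score <- score + w[[k]] * hit
      if (k != "generic") nongeneric_hit <- nongeneric_hit | hit
    }
    better <- score > best_score
    second_score <- ifelse(better, best_score, pmax(second_score, score))
    best_cat[better] <- generic_db$category_id[ci]
    best_generic_only[better] <- !nongeneric_hit[better] & score[better] > 0
    best_score <- ifelse(better, score, best_score)
  }
  tibble::tibble(
    clean_name = clean_names,
    category_id = best_cat,
    score = best_score,
    runner_up_margin = best_score - second_score,
    generic_only = best_generic_only
  )
}

#' Score a cleaned name against every generic category
#'
#' @param tokens Character vector of clean tokens (or a single cleaned
#'   string) for one product.
#' @param generic_db Generic database tibble (see [read_generic_db()]).
#' @param config An [enrich_config()].
#' @return Tibble of all candidates, ranked by descending score with a
#'   deterministic lexicographic `category_id` tie-break.
#' @export
score_generic_candidates <- function(tokens, generic_db,
                                     config = enrich_config()) {
  clean <- paste(tokens, collapse = " ")
  w <- config$weights
  cols <- c(type = "pattern_type", specific = "pattern_specific",
            generic = "pattern_generic", brand = "pattern_brand",
            flavor = "pattern_flavor", fat = "pattern_fat")
  score <- numeric(nrow(generic_db))
  for (k in names(cols)) {
    pats <- generic_db[[cols[[k]]]]
    pats[is.na(pats)] <- ""
    hit <- nzchar(pats) &
      vapply(pats, function(p) nzchar(p) &&
               stringr::str_detect(clean, stringr::regex(p)), logical(1),
             USE.NAMES = FALSE)
    score <- score + w[[k]] * hit
  }
  out <- tibble::tibble(category_id = generic_db$category_id, score = score)
  dplyr::arrange(out, dplyr::desc(.data$score), .data$category_id)
}

#' Accept or reject the best-scoring generic candidate
#'
#' @param ranked Ranked candidate tibble from [score_generic_candidates()].
#' @param config An [enrich_config()] carrying `min_score` / `min_margin`.
#' @return One-row tibble: `category_id` (NA if unmatched), `score`,
#'   `runner_up_margin`, and logical flags `ambiguous`, `below_threshold`.
#' @export
classify_generic <- function(ranked, config = enrich_config()) {
  if (nrow(ranked) == 0L || ranked$score[1L] < config$min_score) {
    return(tibble::tibble(
      category_id = NA_character_,
      score = if (nrow(ranked)) ranked$score[1L] else 0,
      runner_up_margin = NA_real_,
      ambiguous = FALSE, below_threshold = TRUE
    ))
  }
  margin <- ranked$score[1L] -
    (if (nrow(ranked) >= 2L) ranked$score[2L] else 0)
  tibble::tibble(
    category_id = ranked$category_id[1L],
    score = ranked$score[1L],
    runner_up_margin = margin,
    ambiguous = margin < config$min_margin,
    below_threshold = FALSE
  )
}

#' Look up a GTIN in the specific product databases
#'
#' Exact-key lookup with source priority `gs1like` > `chemlike` >
#' `offlike`; when several databases hit, the highest-priority source
#' labels the match and the others contribute secondary annotations
#' (ingredients, risk score).
#'
#' @param gtin Normalized 13-digit GTIN string(s).
#' @param specific_dbs Named list of specific database tibbles.
#' @return Tibble with one row per input gtin: `gtin`, `match_source`
#'   (`"specific:<db>"` or NA), `product_name`, nutrient columns from the
#'   primary source, merged `ingredients` and `risk_score`.
#' @export
match_specific <- function(gtin, specific_dbs) {
  priority <- c("gs1like", "chemlike", "offlike")
  priority <- priority[priority %in% names(specific_dbs)]
  out <- tibble::tibble(
    gtin = gtin,
    match_source = NA_character_,
    product_name = NA_character_,
    energy_kj = NA_real_, fat_g = NA_real_,
    protein_g = NA_real_, carbohydrate_g = NA_real_,
    ingredients = NA_character_, risk_score = NA_character_
  )
  for (src in rev(priority)) {  # low priority first; higher overwrites
    db <- specific_dbs[[src]]
    if (is.null(db) || nrow(db) == 0L) next
    i <- match(gtin, db$gtin)
    hit <- !is.na(i)
    if (!any(hit)) next
    out$match_source[hit] <- paste0("specific:", src)
    out$product_name[hit] <- db$product_name[i[hit]]
    for (nut in core_nutrients) {
      if (!nut %in% names(db)) next
      v <- db[[nut]][i[hit]]
      out[[nut]][hit] <- ifelse(is.na(v), out[[nut]][hit], v)
    }
    if ("ingredients" %in% names(db)) {
      ing <- db$ingredients[i[hit]]
      out$ingredients[hit] <- ifelse(is.na(ing), out$ingredients[hit], ing)
    }
    if ("risk_score" %in% names(db)) {
      rs <- db$risk_score[i[hit]]
      out$risk_score[hit] <- ifelse(is.na(rs), out$risk_score[hit], rs)
    }
  }
  out
}

#' Run the full enrichment pipeline on a purchase table
#'
#' Unique products are identified by the (raw item number, raw item name)
#' pair. The pipeline applies, in order: the item-number digit filter
#' (exclude < 3 or > 14 digits), GTIN normalization and cascade lookup in
#' the specific databases, and — for everything without a specific hit —
#' name preprocessing plus regex scoring against the generic database.
#' Specific matches are additionally assigned a generic category by
#' scoring their database product name, so that nutrient values can later
#' be compared across the two sources.
#'
#' @param purchases A purchase table ([read_receipts()] or
#'   [as_purchase_table()]).
#' @param generic_db Generic database tibble.
#' @param specific_dbs Named list of specific database tibbles
#'   (`gs1like`, `chemlike`, `offlike`; any subset).
#' @param config An [enrich_config()].
#' @return An object of class `cpd_enrichment`: list with `matches` (one
#'   row per unique product with source, category, score, QC flags,
#'   extracted attributes and purchase volumes), `lines` (the input lines
#'   joined to their match), and `summary` (one-row tibble of coverage
#'   fractions and per-source counts). `tidy()` returns the match table,
#'   `glance()` the summary row.
#' @export
enrich <- function(purchases, generic_db, specific_dbs = list(),
                   config = enrich_config()) {
  generic_db <- validate_generic_db(generic_db)
  uniq <- purchases |>
    dplyr::group_by(item_number_raw = .data$item_number,
                    item_name_raw = .data$item_name) |>
    dplyr::summarise(n_lines = dplyr::n(),
                     purchase_volume = sum(.data$quantity),
                     .groups = "drop")

  norm <- normalize_item_number(uniq$item_number_raw)
  uniq$item_status <- norm$status
  uniq$gtin <- norm$gtin

  # stage 1: specific-database cascade for GTIN rows
  spec <- match_specific(uniq$gtin, specific_dbs)
  uniq$match_source <- spec$match_source
  uniq$specific_name <- spec$product_name
  uniq$risk_score <- spec$risk_score
  uniq$ingredients <- spec$ingredients
  has_specific <- !is.na(uniq$match_source)
  uniq$gtin[!has_specific & uniq$item_status != "gtin"] <- NA_character_

  # stage 2: generic regex matching. Specific hits are scored via their
  # database product name (for nutrient comparison); everything else via
  # the receipt name.
  name_for_generic <- ifelse(has_specific, uniq$specific_name,
                             uniq$item_name_raw)
  prep <- preprocess_name(name_for_generic, config)
  attrs_receipt <- preprocess_name(uniq$item_name_raw, config)

  uniq_clean <- unique(prep$clean_name)
  scored <- score_names_against_db(uniq_clean, generic_db, config)
  sc <- scored[match(prep$clean_name, scored$clean_name), ]

  accepted <- !is.na(sc$category_id) & sc$score >= config$min_score
  uniq$category_id <- ifelse(accepted, sc$category_id, NA_character_)
  uniq$score <- sc$score
  uniq$runner_up_margin <- ifelse(accepted, sc$runner_up_margin, NA_real_)

  excluded <- uniq$item_status == "excluded"
  uniq$flag_excluded_item_number <- excluded
  uniq$flag_below_threshold <- !has_specific & !accepted
  # QC flags concern the name-matching route; a specific (GTIN) match is
  # authoritative, so its auxiliary generic score is never flagged
  uniq$flag_ambiguous <- !has_specific & accepted &
    sc$runner_up_margin < config$min_margin
  uniq$flag_greedy <- !has_specific & accepted & sc$generic_only

  uniq$match_source[is.na(uniq$match_source)] <-
    ifelse(accepted[is.na(uniq$match_source)], "generic", "unmatched")
  # an excluded item number can still be name-matched generically; only the
  # GTIN route is closed to it, so no gtin may be attached
  uniq$gtin[excluded] <- NA_character_

  uniq <- dplyr::bind_cols(
    uniq,
    attrs_receipt[, c("clean_name", "weight_g", "volume_ml", "pack_count",
                      "organic", "origin")]
  )
  uniq$flags <- apply(
    cbind(
      ifelse(uniq$flag_excluded_item_number, "excluded_item_number", NA),
      ifelse(uniq$flag_greedy, "greedy", NA),
      ifelse(uniq$flag_ambiguous, "ambiguous", NA),
      ifelse(uniq$flag_below_threshold, "below_threshold", NA)
    ), 1L,
    function(r) paste(stats::na.omit(r), collapse = ",")
  )

  # line-level join
  lines <- purchases |>
    dplyr::left_join(
      uniq |>
        dplyr::select("item_number_raw", "item_name_raw", "match_source",
                      "category_id", "gtin", "risk_score") |>
        dplyr::left_join(
          generic_db[, intersect(c("category_id", "food_group", "is_food"),
                                 names(generic_db))],
          by = "category_id"
        ),
      by = c(item_number = "item_number_raw", item_name = "item_name_raw")
    )

  matched <- uniq$match_source != "unmatched"
  n_unique <- nrow(uniq)
  summary <- tibble::tibble(
    n_unique_products = n_unique,
    n_total_lines = nrow(purchases),
    total_volume = sum(uniq$purchase_volume),
    frac_unique_matched = mean(matched),
    frac_total_matched = sum(uniq$purchase_volume[matched]) /
      sum(uniq$purchase_volume),
    n_specific_direct = sum(startsWith(uniq$match_source, "specific")),
    n_generic = sum(uniq$match_source == "generic"),
    n_unmatched = sum(uniq$match_source == "unmatched"),
    n_excluded_item_number = sum(uniq$flag_excluded_item_number),
    n_ambiguous = sum(uniq$flag_ambiguous),
    n_greedy = sum(uniq$flag_greedy)
  )

  structure(list(matches = uniq, lines = lines, summary = summary,
                 config = config),
            class = "cpd_enrichment")
}

#' @export
print.cpd_enrichment <- function(x, ...) {
  s <- x$summary
  cat("<cpd_enrichment>\n")
  cat(sprintf("  %d unique products over %d lines\n",
              s$n_unique_products, s$n_total_lines))
  cat(sprintf("  matched: %.1f%% of unique products, %.1f%% of volume\n",
              100 * s$frac_unique_matched, 100 * s$frac_total_matched))
  cat(sprintf("  specific: %d  generic: %d  unmatched: %d\n",
              s$n_specific_direct, s$n_generic, s$n_unmatched))
  invisible(x)
}

#' @export
tidy.cpd_enrichment <- function(x, ...) x$matches

#' @export
glance.cpd_enrichment <- function(x, ...) x$summary

#' Export the manual-review queue
#'
#' All products flagged greedy, ambiguous or unmatched (below threshold or
#' excluded item number), sorted by purchase volume descending so the
#' highest-impact names come first.
#'
#' @param enrichment A `cpd_enrichment` object (or its match table).
#' @return Tibble of flagged products with their scores and flags.
#' @export
export_review_queue <- function(enrichment) {
  matches <- if (inherits(enrichment, "cpd_enrichment")) {
    enrichment$matches
  } else {
    enrichment
  }
  matches |>
    dplyr::filter(.data$flag_greedy | .data$flag_ambiguous |
                    .data$match_source == "unmatched") |>
    dplyr::arrange(dplyr::desc(.data$purchase_volume),
                   .data$item_name_raw) |>
    dplyr::select("item_number_raw", "item_name_raw", "match_source",
                  "category_id", "score", "runner_up_margin", "flags",
                  "purchase_volume", "n_lines")
}
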