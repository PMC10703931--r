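# Shared fixtures, built in code.

# a tiny receipts data frame in the file schema
make_receipts_df <- function() {
  tibble::tibble(
    participant_id = c("p1", "p1", "p1", "p2"),
    retailer_id = c("r1", "r1", "r2", "r1"),
    purchase_datetime = c("2022-01-05T10:00:00", "2022-01-05T10:00:00",
                          "2022-01-09T17:30:00", "2022-02-01T08:15:00"),
    item_number = c("5701234567899", "123456", "5700000000001", "42421"),
    item_name = c("norvia milk skimmed 1l", "bread wholegrain 500g",
                  "apples 6-pack", "cola 1.5l"),
    unit_price_dkk = c(12.50, 18.00, 24.95, 22.00),
    quantity = c(1L, 2L, 1L, 3L),
    discount_dkk = c(0, 5.00, 0, 0)
  )
}

# two-group, four-category generic database exercising type/specific/fat
# pattern columns
make_generic_db <- function() {
  tibble::tibble(
    category_id = c("milk_skimmed", "milk_whole", "bread_wholegrain",
                    "bread_white"),
    category_name = c("milk skimmed", "milk whole", "bread wholegrain",
                      "bread white"),
    is_food = TRUE,
    food_group = c("milk products", "milk products", "bread", "bread"),
    energy_kj = c(150, 270, 1000, 1100),
    fat_g = c(0.1, 3.5, 3, 2),
    protein_g = c(3.5, 3.4, 9, 8),
    carbohydrate_g = c(5, 4.7, 45, 50),
    pattern_brand = "",
    pattern_type = c("\\bmilk\\b", "\\bmilk\\b", "\\bbread\\b",
                     "\\bbread\\b"),
    pattern_specific = c("", "", "\\bwholegrain\\b", "\\bwhite\\b"),
    pattern_generic = "",
    pattern_flavor = "",
    pattern_fat = c("\\bskimmed\\b", "\\bwhole\\b", "", "")
  )
}

make_gtin <- function(payload12) {
  paste0(payload12, cpdenrich::gtin_check_digit(payload12))
}

make_specific_db <- function(gtins, names, energy, source = "gs1like") {
  tibble::tibble(
    gtin = gtins, product_name = names,
    energy_kj = energy, fat_g = 1, protein_g = 2, carbohydrate_g = 3,
    ingredients = "water;salt",
    risk_score = if (source == "chemlike") "B" else NA_character_,
    gtin_valid = TRUE, source_db = source
  )
}

# enriched-style line table with true group labels, bypassing enrichment;
# used by coverage tests that only need group-labelled lines
lines_with_truth <- function(cohort) {
  dplyr::left_join(
    cohort$purchases,
    dplyr::select(cohort$truth$observed_products,
                  "item_number", "item_name",
                  food_group = "group", "is_food"),
    by = c("item_number", "item_name")
  )
}

small_config <- function(...) {
  defaults <- list(n_participants = 20, n_retailers = 6, n_products = 150,
                   months = 6, seed = 7)
  args <- utils::modifyList(defaults, list(...))
  do.call(cpdenrich::cohort_config, args)
}
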