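# Seeded synthetic cohort: product catalog, generic/specific databases and
# multi-year receipt streams with known ground truth. The generator emulates
# the statistical structure of multi-retailer digital-receipt data: Zipf-
# skewed product popularity, Dirichlet heterogeneity in food-group
# preferences and retailer loyalty, partial database coverage, noisy
# abbreviated receipt names, and retailer assortments that do not all carry
# every product group.

food_group_defs <- tibble::tibble(
  group = c("bread", "milk products", "vegetables raw", "red meat",
            "alcohol", "fish", "poultry", "fruit", "cheese", "spreads",
            "eggs", "pasta and rice", "breakfast cereals", "sweets",
            "soft drinks", "coffee and tea", "frozen vegetables",
            "canned goods", "snacks", "sauces"),
  stem = c("bread", "milk", "tomato", "beef", "beer", "salmon", "chicken",
           "apple", "cheese", "butter", "egg", "pasta", "cereal", "choco",
           "cola", "coffee", "peas", "beans", "chips", "ketchup"),
  is_food = TRUE
)

nonfood_group_defs <- tibble::tibble(
  group = c("tobacco", "cleaning", "dental"),
  stem = c("cigarette", "detergent", "toothpaste"),
  is_food = FALSE
)

category_descriptors <- c("classic", "wholegrain", "rustic", "premium",
                          "farm", "wild", "smoked", "mini", "extra", "fine")
fat_descriptors <- c("skimmed", "whole", "semi", "low-fat")
flavor_descriptors <- c("vanilla", "strawberry", "caramel", "lemon")
brand_pool <- c("norvia", "dankost", "grona", "vestfeld", "solmark",
                "byhavn", "fjordly", "almue")

#' Configuration for the synthetic purchase cohort
#'
#' Returns a validated configuration list. The defaults describe a
#' mid-sized Danish-style multi-retailer cohort: 34 retailers, 20 food
#' product groups plus a few non-food groups (tobacco-like, cleaning,
#' dental), Zipf-skewed product popularity, on average 8.4 receipts per
#' participant-month, and roughly ten lines per receipt.
#'
#' @param n_participants Number of participants.
#' @param n_retailers Number of retailers (default 34).
#' @param n_products Number of unique catalog products.
#' @param zipf_exponent Popularity skew exponent (> 0).
#' @param n_food_groups Number of food product groups used (<= 20).
#' @param n_nonfood_groups Number of non-food groups (<= 3); the first is a
#'   tobacco-like group carried by only a minority of retailers.
#' @param categories_per_group Generic categories per group.
#' @param group_preference_concentration Dirichlet concentration for
#'   per-participant group preferences (small = heterogeneous).
#' @param loyalty_concentration Dirichlet concentration for per-participant
#'   retailer-choice probabilities (small = loyal to few retailers).
#' @param months Study length in calendar months.
#' @param start_month First study month, `"YYYY-MM"`.
#' @param receipts_per_month_mean Mean receipts per active participant-month.
#' @param lines_per_receipt_mean Mean purchase lines per receipt.
#' @param specific_db_coverage Named fractions of the catalog present in
#'   each specific database (`gs1like`, `chemlike`, `offlike`).
#' @param popularity_weighted_coverage If `TRUE`, database inclusion is
#'   popularity-weighted (frequently bought products more likely covered).
#' @param nutrient_noise_sigma Log-normal sigma for the multiplicative
#'   deviation of brand-specific nutrient values from the generic category
#'   average. The default 0.39 makes the median modified relative
#'   difference of a matched nutrient about 0.23.
#' @param name_noise_level Probability that a retailer's printed name for a
#'   product is corrupted (abbreviated/truncated/unit-token noise).
#' @param internal_code_prob Fraction of products whose receipts print a
#'   short supplier-internal code instead of the GTIN.
#' @param assortment_coverage Fraction of the catalog each retailer
#'   carries (popularity-weighted sampling).
#' @param restricted_retailer_frac Fraction of retailers that carry the
#'   tobacco-like restricted group.
#' @param inactive_month_prob Per participant-month probability of zero
#'   purchases.
#' @param missing_nutrient_prob Probability a nutrient value is absent in
#'   the crowd-sourced (`offlike`) database.
#' @param seed Integer seed driving every stage (stage generators use fixed
#'   offsets from it).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 200,
                          n_retailers = 34,
                          n_products = 2000,
                          zipf_exponent = 1.1,
                          n_food_groups = 20,
                          n_nonfood_groups = 3,
                          categories_per_group = 3,
                          group_preference_concentration = 2,
                          loyalty_concentration = 0.5,
                          months = 24,
                          start_month = "2021-01",
                          receipts_per_month_mean = 8.4,
                          lines_per_receipt_mean = 9.8,
                          specific_db_coverage = list(gs1like = 0.5,
                                                      chemlike = 0.2,
                                                      offlike = 0.3),
                          popularity_weighted_coverage = TRUE,
                          nutrient_noise_sigma = 0.39,
                          name_noise_level = 0.1,
                          internal_code_prob = 0.2,
                          assortment_coverage = 0.8,
                          restricted_retailer_frac = 0.3,
                          inactive_month_prob = 0.1,
                          missing_nutrient_prob = 0.2,
                          seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_retailers = as.integer(n_retailers),
    n_products = as.integer(n_products),
    zipf_exponent = as.numeric(zipf_exponent),
    n_food_groups = as.integer(n_food_groups),
    n_nonfood_groups = as.integer(n_nonfood_groups),
    categories_per_group = as.integer(categories_per_group),
    group_preference_concentration = as.numeric(group_preference_concentration),
    loyalty_concentration = as.numeric(loyalty_concentration),
    months = as.integer(months),
    start_month = as.character(start_month),
    receipts_per_month_mean = as.numeric(receipts_per_month_mean),
    lines_per_receipt_mean = as.numeric(lines_per_receipt_mean),
    specific_db_coverage = lapply(specific_db_coverage, as.numeric),
    popularity_weighted_coverage = isTRUE(popularity_weighted_coverage),
    nutrient_noise_sigma = as.numeric(nutrient_noise_sigma),
    name_noise_level = as.numeric(name_noise_level),
    internal_code_prob = as.numeric(internal_code_prob),
    assortment_coverage = as.numeric(assortment_coverage),
    restricted_retailer_frac = as.numeric(restricted_retailer_frac),
    inactive_month_prob = as.numeric(inactive_month_prob),
    missing_nutrient_prob = as.numeric(missing_nutrient_prob),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  stopifnot(
    cfg$n_participants >= 1L, cfg$n_retailers >= 1L, cfg$n_products >= 1L,
    cfg$zipf_exponent > 0, cfg$n_food_groups >= 1L,
    cfg$n_food_groups <= nrow(food_group_defs),
    cfg$n_nonfood_groups >= 0L,
    cfg$n_nonfood_groups <= nrow(nonfood_group_defs),
    cfg$categories_per_group >= 1L, cfg$months >= 1L,
    grepl("^\\d{4}-\\d{2}$", cfg$start_month),
    cfg$receipts_per_month_mean > 0, cfg$lines_per_receipt_mean >= 1
  )
  fracs <- c(unlist(cfg$specific_db_coverage), cfg$name_noise_level,
             cfg$internal_code_prob, cfg$assortment_coverage,
             cfg$restricted_retailer_frac, cfg$inactive_month_prob,
             cfg$missing_nutrient_prob)
  if (any(fracs < 0 | fracs > 1)) {
    stop("all coverage/probability parameters must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Read / write a cohort configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` invisibly returns the path.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cohort_config, vals)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# per-stage seeds derived from the global seed by fixed offsets, so a stage
# keeps its stream when downstream settings change
stage_seed <- function(cfg, stage) {
  offs <- c(catalog = 101L, databases = 202L, receipts = 303L)
  (cfg$seed + offs[[stage]]) %% .Machine$integer.max
}

group_table <- function(cfg) {
  dplyr::bind_rows(
    food_group_defs[seq_len(cfg$n_food_groups), ],
    nonfood_group_defs[seq_len(cfg$n_nonfood_groups), ]
  )
}

#' Generate the synthetic product catalog
#'
#' Each product gets a valid GTIN-13, a clean canonical name built from
#' brand / type-stem / descriptor / size tokens, a true generic category
#' (nested in a food or non-food product group) and a Zipf popularity
#' weight. Deterministic given the config seed.
#'
#' @param config A [cohort_config()].
#' @return A list with `products` (one row per product: `product_id`,
#'   `gtin`, `internal_code`, `uses_internal_code`, `canonical_name`,
#'   `category_id`, `group`, `is_food`, `zipf_weight`, `unit_price_ore`)
#'   and `categories` (the category skeleton the generic database is built
#'   from).
#' @export
generate_catalog <- function(config) {
  validate_cohort_config(config)
  set.seed(stage_seed(config, "catalog"))
  groups <- group_table(config)

  # category skeleton: within a group, categories share the type stem and
  # differ by a descriptor token; dairy-style groups differ by fat level,
  # the sweets group by flavor, everything else by a specific descriptor
  categories <- purrr::pmap_dfr(
    list(groups$group, groups$stem, groups$is_food, seq_len(nrow(groups))),
    function(group, stem, is_food, gi) {
      k <- config$categories_per_group
      kind <- if (stem %in% c("milk", "cheese")) "fat"
              else if (stem == "choco") "flavor" else "specific"
      pool <- switch(kind, fat = fat_descriptors, flavor = flavor_descriptors,
                     specific = category_descriptors)
      k <- min(k, length(pool))
      tibble::tibble(
        category_id = sprintf("cat_%02d_%02d", gi, seq_len(k)),
        category_name = paste(stem, pool[seq_len(k)]),
        group = group, stem = stem, is_food = is_food,
        descriptor = pool[seq_len(k)], descriptor_kind = kind
      )
    }
  )

  n <- config$n_products
  cat_idx <- sample.int(nrow(categories), n, replace = TRUE)
  ranks <- sample.int(n)                       # popularity rank permutation
  w <- ranks^(-config$zipf_exponent)
  w <- w / sum(w)

  brand <- sample(brand_pool, n, replace = TRUE)
  has_brand <- runif(n) < 0.5
  size_tok <- sample(c("500g", "1kg", "250g", "1l", "500ml", "6-pack", ""),
                     n, replace = TRUE)
  cat_rows <- categories[cat_idx, ]
  name <- trimws(paste(
    ifelse(has_brand, brand, ""),
    cat_rows$stem, cat_rows$descriptor, size_tok
  ))
  name <- gsub("\\s+", " ", name)

  payload <- sprintf("57%010d", seq_len(n))
  gtin <- paste0(payload, gtin_check_digit(payload))
  internal_code <- sprintf("%06d", sample.int(899999L, n) + 100000L)

  price_ore <- pmax(100L, as.integer(round(
    rlnorm(n, meanlog = log(2170), sdlog = 0.45)
  )))

  products <- tibble::tibble(
    product_id = sprintf("prod%05d", seq_len(n)),
    gtin = gtin,
    internal_code = internal_code,
    uses_internal_code = runif(n) < config$internal_code_prob,
    canonical_name = name,
    category_id = cat_rows$category_id,
    group = cat_rows$group,
    is_food = cat_rows$is_food,
    zipf_weight = w,
    unit_price_ore = price_ore
  )
  list(products = products, categories = categories)
}

#' Generate generic and specific product databases for a catalog
#'
#' The generic database has one record per true category with regex
#' pattern columns built from the catalog's token vocabulary (type stem in
#' `pattern_type`; the distinguishing descriptor in `pattern_specific`,
#' `pattern_fat` or `pattern_flavor` depending on the group). Each specific
#' database contains a (optionally popularity-weighted) random fraction of
#' the catalog with nutrient values perturbed multiplicatively from the
#' category average by log-normal noise with `nutrient_noise_sigma` — this
#' perturbation is the ground truth for the nutrient-concordance stage.
#'
#' @param catalog Result of [generate_catalog()].
#' @param config A [cohort_config()].
#' @return A list with `generic_db` (tibble) and `specific_dbs` (named list
#'   of tibbles: `gs1like`, `chemlike`, `offlike`).
#' @export
generate_databases <- function(catalog, config) {
  validate_cohort_config(config)
  set.seed(stage_seed(config, "databases"))
  categories <- catalog$categories
  products <- catalog$products
  nc <- nrow(categories)

  fat <- ifelse(categories$is_food, round(runif(nc, 0, 30), 1), 0)
  protein <- ifelse(categories$is_food, round(runif(nc, 1, 25), 1), 0)
  carb <- ifelse(categories$is_food, round(runif(nc, 1, 60), 1), 0)
  energy <- round(37 * fat + 17 * (protein + carb))

  bound <- function(x) ifelse(nzchar(x), paste0("\\b(", x, ")\\b"), "")
  generic_db <- tibble::tibble(
    category_id = categories$category_id,
    category_name = categories$category_name,
    is_food = categories$is_food,
    food_group = categories$group,
    energy_kj = energy, fat_g = fat, protein_g = protein,
    carbohydrate_g = carb,
    pattern_brand = "",
    pattern_type = bound(categories$stem),
    pattern_specific = bound(
      ifelse(categories$descriptor_kind == "specific",
             categories$descriptor, "")),
    pattern_generic = "",
    pattern_flavor = bound(
      ifelse(categories$descriptor_kind == "flavor",
             categories$descriptor, "")),
    pattern_fat = bound(
      ifelse(categories$descriptor_kind == "fat",
             categories$descriptor, ""))
  )

  cat_nut <- generic_db[, c("category_id", core_nutrients)]
  make_specific <- function(source_db, coverage) {
    m <- round(coverage * nrow(products))
    if (m == 0L) {
      return(tibble::tibble(
        gtin = character(), product_name = character(),
        energy_kj = numeric(), fat_g = numeric(), protein_g = numeric(),
        carbohydrate_g = numeric(), ingredients = character(),
        risk_score = character(), gtin_valid = logical(),
        source_db = character()
      ))
    }
    prob <- if (config$popularity_weighted_coverage) products$zipf_weight
            else NULL
    keep <- sort(sample.int(nrow(products), m, prob = prob))
    sel <- products[keep, ]
    db <- dplyr::left_join(
      sel[, c("gtin", "canonical_name", "category_id")],
      cat_nut, by = "category_id"
    )
    sigma <- config$nutrient_noise_sigma
    for (nut in core_nutrients) {
      db[[nut]] <- db[[nut]] * exp(rnorm(m, 0, sigma))
      if (source_db == "offlike" && config$missing_nutrient_prob > 0) {
        db[[nut]][runif(m) < config$missing_nutrient_prob] <- NA_real_
      }
    }
    tibble::tibble(
      gtin = db$gtin,
      product_name = db$canonical_name,
      energy_kj = db$energy_kj, fat_g = db$fat_g,
      protein_g = db$protein_g, carbohydrate_g = db$carbohydrate_g,
      ingredients = paste("water", "salt", sep = ";"),
      risk_score = if (source_db == "chemlike") {
        sample(c("A", "B", "C"), m, replace = TRUE, prob = c(0.5, 0.3, 0.2))
      } else NA_character_,
      gtin_valid = TRUE,
      source_db = source_db
    )
  }

  cov <- config$specific_db_coverage
  list(
    generic_db = generic_db,
    specific_dbs = list(
      gs1like = make_specific("gs1like", cov$gs1like %||% 0),
      chemlike = make_specific("chemlike", cov$chemlike %||% 0),
      offlike = make_specific("offlike", cov$offlike %||% 0)
    )
  )
}

# row-wise Dirichlet draws; at extreme concentrations the gamma draws can
# underflow to an all-zero row, which degenerates to a one-hot vector
rdirichlet_rows <- function(n, shape, ncol = NULL) {
  if (is.null(ncol)) ncol <- length(shape) / n
  m <- matrix(rgamma(n * ncol, shape = shape), nrow = n)
  zero <- rowSums(m) == 0
  if (any(zero)) {
    for (i in which(zero)) m[i, sample.int(ncol, 1L)] <- 1
  }
  m / rowSums(m)
}

# receipt-name corruption operators: vowel-dropping abbreviation,
# truncation, unit-token injection, case mangling
corrupt_names <- function(names) {
  op <- sample.int(4L, length(names), replace = TRUE)
  out <- names
  v <- op == 1L
  if (any(v)) {
    out[v] <- vapply(strsplit(names[v], " ", fixed = TRUE), function(ws) {
      paste(paste0(substr(ws, 1, 1),
                   gsub("[aeiouy]", "", substring(ws, 2))), collapse = " ")
    }, character(1))
  }
  t <- op == 2L
  out[t] <- substr(names[t], 1L, 20L)
  u <- op == 3L
  if (any(u)) {
    out[u] <- paste(names[u],
                    sample(c("x2", "kampagne", "tilbud", "350g"),
                           sum(u), replace = TRUE))
  }
  m <- op == 4L
  out[m] <- toupper(names[m])
  out
}

#' Generate synthetic receipt streams
#'
#' For every participant-month (unless inactive) the generator draws a
#' Poisson number of receipts; each receipt draws a retailer from the
#' participant's loyalty vector and a Poisson(+1) number of lines; each
#' line draws a product group from the participant's true group
#' preferences (restricted to groups the retailer carries) and then a
#' product within the group by Zipf weight over the retailer's assortment.
#' Printed item names are per-retailer display names, corrupted with
#' probability `name_noise_level`; item numbers are the product GTIN or,
#' for a fraction of products, a supplier-internal code.
#'
#' @param catalog Result of [generate_catalog()].
#' @param config A [cohort_config()].
#' @return A list with `purchases` (a purchase table), `participant_truth`
#'   (list of `preferences` and `loyalty` long tibbles),
#'   `observed_products` (the (item_number, item_name) to true product
#'   mapping with purchase volumes), and `assortment` (long tibble of
#'   retailer x product).
#' @export
generate_receipts <- function(catalog, config) {
  validate_cohort_config(config)
  set.seed(stage_seed(config, "receipts"))
  products <- catalog$products
  groups <- group_table(config)
  ng <- nrow(groups)
  np <- config$n_participants
  nr <- config$n_retailers
  retailer_ids <- sprintf("ret%02d", seq_len(nr))
  participant_ids <- sprintf("part%04d", seq_len(np))

  # participant truth: Dirichlet preferences over groups (food groups more
  # popular than non-food) and Dirichlet loyalty over retailers
  base_w <- ifelse(groups$is_food, 1, 0.3)
  base_w <- base_w / sum(base_w)
  alpha_pref <- config$group_preference_concentration * base_w * ng
  pref <- rdirichlet_rows(np, rep(alpha_pref, each = np))
  loy <- rdirichlet_rows(np, config$loyalty_concentration,
                         ncol = nr)

  # retailer assortments: popularity-weighted subsets; the tobacco-like
  # restricted group is carried by a minority of retailers only
  n_keep <- max(1L, round(config$assortment_coverage * nrow(products)))
  assort <- matrix(FALSE, nrow = nr, ncol = nrow(products))
  for (r in seq_len(nr)) {
    keep <- sample.int(nrow(products), n_keep, prob = products$zipf_weight)
    assort[r, keep] <- TRUE
  }
  restricted_group <- if (config$n_nonfood_groups >= 1L) {
    nonfood_group_defs$group[1L]
  } else NA_character_
  if (!is.na(restricted_group)) {
    carriers <- sample.int(nr, max(1L, ceiling(
      config$restricted_retailer_frac * nr)))
    restricted_prod <- products$group == restricted_group
    assort[-carriers, restricted_prod] <- FALSE
  }

  # per-retailer display names, corrupted with probability name_noise_level
  pairs <- which(assort, arr.ind = TRUE)
  display <- tibble::tibble(
    retailer = pairs[, 1L], product = pairs[, 2L],
    item_name = products$canonical_name[pairs[, 2L]]
  )
  noisy <- runif(nrow(display)) < config$name_noise_level
  if (any(noisy)) {
    display$item_name[noisy] <- corrupt_names(display$item_name[noisy])
  }

  # participant-month activity and receipt counts
  pm <- tidyr::expand_grid(p = seq_len(np), m = seq_len(config$months))
  active <- runif(nrow(pm)) >= config$inactive_month_prob
  n_rec <- ifelse(active, rpois(nrow(pm), config$receipts_per_month_mean), 0L)
  rec <- pm[rep.int(seq_len(nrow(pm)), n_rec), ]
  if (nrow(rec) == 0L) {
    return(list(
      purchases = as_purchase_table(tibble::tibble(
        participant_id = character(), retailer_id = character(),
        purchase_datetime = character(), item_number = character(),
        item_name = "x", unit_price_dkk = numeric(), quantity = integer(),
        discount_dkk = numeric())[0, ]),
      participant_truth = list(
        preferences = tidyr::expand_grid(
          participant_id = participant_ids, group = groups$group) |>
          dplyr::mutate(true_proportion = as.vector(t(pref))),
        loyalty = tidyr::expand_grid(
          participant_id = participant_ids, retailer_id = retailer_ids) |>
          dplyr::mutate(true_loyalty = as.vector(t(loy)))
      ),
      observed_products = tibble::tibble(),
      assortment = display[, c("retailer", "product")]
    ))
  }

  # retailer per receipt, sampled per participant from the loyalty vector
  rec$r <- unlist(lapply(split(seq_len(nrow(rec)), rec$p), function(idx) {
    p <- rec$p[idx[1L]]
    sample.int(nr, length(idx), replace = TRUE, prob = loy[p, ])
  }), use.names = FALSE)[order(order(rec$p))]

  # receipt timestamps: uniform within the calendar month
  start <- as.Date(paste0(config$start_month, "-01"))
  month_start <- seq(start, by = "month", length.out = config$months + 1L)
  m0 <- as.numeric(month_start[rec$m])
  m1 <- as.numeric(month_start[rec$m + 1L])
  day <- as.Date(floor(m0 + runif(nrow(rec)) * (m1 - m0 - 1)),
                 origin = "1970-01-01")
  secs <- 8 * 3600 + floor(runif(nrow(rec)) * 13 * 3600)
  rec$datetime <- as.POSIXct(as.numeric(as.POSIXct(day, tz = "UTC")) + secs,
                             tz = "UTC", origin = "1970-01-01")

  n_lines <- 1L + rpois(nrow(rec), max(config$lines_per_receipt_mean - 1, 0))
  lines <- rec[rep.int(seq_len(nrow(rec)), n_lines), ]

  # group per line from participant preferences; lines whose group the
  # retailer does not carry are re-drawn from the retailer's available
  # groups with renormalized preferences
  grp_of_prod <- match(products$group, groups$group)
  avail <- matrix(FALSE, nrow = nr, ncol = ng)
  for (r in seq_len(nr)) {
    avail[r, unique(grp_of_prod[assort[r, ]])] <- TRUE
  }
  lines$g <- unlist(lapply(split(seq_len(nrow(lines)), lines$p),
                           function(idx) {
    p <- lines$p[idx[1L]]
    sample.int(ng, length(idx), replace = TRUE, prob = pref[p, ])
  }), use.names = FALSE)[order(order(lines$p))]
  bad <- !avail[cbind(lines$r, lines$g)]
  if (any(bad)) {
    key <- paste(lines$p[bad], lines$r[bad])
    for (idx in split(which(bad), key)) {
      p <- lines$p[idx[1L]]; r <- lines$r[idx[1L]]
      ok <- which(avail[r, ])
      lines$g[idx] <- ok[sample.int(length(ok), length(idx), replace = TRUE,
                                    prob = pref[p, ok])]
    }
  }

  # product per line: Zipf-weighted within (retailer, group) assortment
  lines$prod <- NA_integer_
  key <- paste(lines$r, lines$g)
  for (idx in split(seq_len(nrow(lines)), key)) {
    r <- lines$r[idx[1L]]; g <- lines$g[idx[1L]]
    pool <- which(assort[r, ] & grp_of_prod == g)
    if (length(pool) == 1L) {
      lines$prod[idx] <- pool
    } else {
      lines$prod[idx] <- pool[sample.int(
        length(pool), length(idx), replace = TRUE,
        prob = products$zipf_weight[pool])]
    }
  }

  lines <- dplyr::left_join(
    lines, display, by = c("r" = "retailer", "prod" = "product")
  )
  qty <- 1L + rpois(nrow(lines), 0.4)
  price <- products$unit_price_ore[lines$prod]
  disc <- ifelse(runif(nrow(lines)) < 0.1,
                 as.integer(round(price * qty * runif(nrow(lines), 0.1, 0.5))),
                 0L)
  purchases <- tibble::tibble(
    participant_id = participant_ids[lines$p],
    retailer_id = retailer_ids[lines$r],
    purchase_datetime = lines$datetime,
    item_number = ifelse(products$uses_internal_code[lines$prod],
                         products$internal_code[lines$prod],
                         products$gtin[lines$prod]),
    item_name = lines$item_name,
    unit_price_ore = as.integer(price),
    quantity = as.integer(qty),
    discount_ore = as.integer(disc)
  )
  validate_purchase_table(purchases)

  observed <- tibble::tibble(
    item_number = purchases$item_number,
    item_name = purchases$item_name,
    product_id = products$product_id[lines$prod],
    quantity = purchases$quantity
  ) |>
    dplyr::group_by(.data$item_number, .data$item_name, .data$product_id) |>
    dplyr::summarise(n_lines = dplyr::n(),
                     total_quantity = sum(.data$quantity),
                     .groups = "drop") |>
    dplyr::left_join(
      products[, c("product_id", "category_id", "group", "is_food")],
      by = "product_id"
    )

  list(
    purchases = purchases,
    participant_truth = list(
      preferences = tidyr::expand_grid(
        participant_id = participant_ids, group = groups$group) |>
        dplyr::mutate(true_proportion = as.vector(t(pref))),
      loyalty = tidyr::expand_grid(
        participant_id = participant_ids, retailer_id = retailer_ids) |>
        dplyr::mutate(true_loyalty = as.vector(t(loy)))
    ),
    observed_products = observed,
    assortment = display[, c("retailer", "product")]
  )
}

#' Generate a complete synthetic cohort
#'
#' Composes [generate_catalog()], [generate_databases()] and
#' [generate_receipts()] into one object with ground truth, and optionally
#' writes every table to an output directory in the interchange formats.
#'
#' @param config A [cohort_config()].
#' @param out_dir Optional directory; when given, receipts (CSV), the
#'   generic and specific databases (CSV) and the truth tables (CSV) are
#'   written there.
#' @return An object of class `cpd_cohort`: a list with `purchases`,
#'   `generic_db`, `specific_dbs`, `products`, `categories`, and `truth`
#'   (`products`, `preferences`, `loyalty`, `observed_products`).
#' @export
generate_cohort <- function(config = cohort_config(), out_dir = NULL) {
  validate_cohort_config(config)
  catalog <- generate_catalog(config)
  dbs <- generate_databases(catalog, config)
  rec <- generate_receipts(catalog, config)
  cohort <- structure(list(
    purchases = rec$purchases,
    generic_db = dbs$generic_db,
    specific_dbs = dbs$specific_dbs,
    products = catalog$products,
    categories = catalog$categories,
    truth = list(
      products = catalog$products[, c("product_id", "gtin", "category_id",
                                      "group", "is_food", "zipf_weight")],
      preferences = rec$participant_truth$preferences,
      loyalty = rec$participant_truth$loyalty,
      observed_products = rec$observed_products
    ),
    config = config
  ), class = "cpd_cohort")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table(cohort$purchases, file.path(out_dir, "receipts.csv"))
    write_table(cohort$generic_db, file.path(out_dir, "generic_db.csv"))
    for (nm in names(cohort$specific_dbs)) {
      write_table(cohort$specific_dbs[[nm]],
                  file.path(out_dir, paste0("specific_", nm, ".csv")))
    }
    write_table(cohort$truth$products, file.path(out_dir, "truth_products.csv"))
    write_table(cohort$truth$preferences,
                file.path(out_dir, "truth_preferences.csv"))
    write_table(cohort$truth$loyalty, file.path(out_dir, "truth_loyalty.csv"))
    write_table(cohort$truth$observed_products,
                file.path(out_dir, "truth_observed_products.csv"))
    write_cohort_config(config, file.path(out_dir, "config.yaml"))
  }
  cohort
}

#' @export
print.cpd_cohort <- function(x, ...) {
  cat("<cpd_cohort>\n")
  cat("  participants:", x$config$n_participants,
      " retailers:", x$config$n_retailers,
      " products:", x$config$n_products, "\n")
  cat("  purchase lines:", nrow(x$purchases),
      " receipts:", count_receipts(x$purchases), "\n")
  invisible(x)
}
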