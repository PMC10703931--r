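# Name preprocessing, regex scoring, thresholds, the GTIN cascade and the
# full enrichment pipeline.

test_that("preprocessing extracts units, pack counts and organic markers", {
  out <- preprocess_name("apples 6-pack")
  expect_equal(out$clean_name, "apples")
  expect_equal(out$pack_count, 6L)

  out <- preprocess_name("ØKO skimmed milk 1l")
  expect_equal(out$clean_name, "skimmed milk")
  expect_true(out$organic)
  expect_equal(out$volume_ml, 1000)

  out <- preprocess_name("dansk beef 1,5 kg")
  expect_equal(out$clean_name, "beef")
  expect_equal(out$weight_g, 1500)
  expect_equal(out$origin, "dansk")

  # a name that is nothing but stripped material yields empty tokens
  out <- preprocess_name("500g 6-pack")
  expect_equal(out$clean_name, "")
})

test_that("abbreviations expand and stopwords drop, order preserved", {
  cfg <- enrich_config(stopwords = "tilbud",
                       abbreviations = c(mlk = "milk"))
  out <- preprocess_name("skimmed mlk tilbud", cfg)
  expect_equal(out$clean_name, "skimmed milk")
})

test_that("scoring implements the weighted pattern-hit sum with tie-break", {
  db <- make_generic_db()
  # "skimmed milk": type hit (4) for both milk categories, fat hit (+1)
  # only for skimmed -> 5 vs 4
  ranked <- score_generic_candidates(c("skimmed", "milk"), db)
  expect_equal(ranked$category_id[1:2], c("milk_skimmed", "milk_whole"))
  expect_equal(ranked$score[1:2], c(5, 4))

  # no hits anywhere -> all scores 0
  ranked0 <- score_generic_candidates("zzz", db)
  expect_true(all(ranked0$score == 0))
  # equal scores are returned in lexicographic category_id order
  expect_equal(ranked0$category_id, sort(db$category_id))
})

test_that("classification thresholds and flags follow the config", {
  db <- make_generic_db()
  ranked <- score_generic_candidates(c("skimmed", "milk"), db)  # 5 vs 4
  strict <- classify_generic(ranked, enrich_config(min_margin = 2))
  expect_equal(strict$category_id, "milk_skimmed")
  expect_true(strict$ambiguous)
  loose <- classify_generic(ranked, enrich_config(min_margin = 1))
  expect_false(loose$ambiguous)

  low <- classify_generic(
    tibble::tibble(category_id = c("a", "b"), score = c(2, 0)),
    enrich_config(min_score = 4))
  expect_true(is.na(low$category_id))
  expect_true(low$below_threshold)
})

test_that("a win on generic-descriptor evidence alone is flagged greedy", {
  db <- make_generic_db()[1, ]
  db$pattern_type <- ""
  db$pattern_fat <- ""
  db$pattern_generic <- "\\b(dairy|drink)\\b"
  cfg <- enrich_config(min_score = 1)
  pt <- as_purchase_table(tibble::tibble(
    participant_id = "p1", retailer_id = "r1",
    purchase_datetime = "2022-01-01T10:00:00", item_number = "111",
    item_name = "dairy drink", unit_price_dkk = 10, quantity = 1L,
    discount_dkk = 0))
  enr <- enrich(pt, db, config = cfg)
  expect_equal(enr$matches$match_source, "generic")
  expect_true(enr$matches$flag_greedy)
  expect_match(enr$matches$flags, "greedy")
})

test_that("GTIN cascade prefers gs1like and merges secondary annotations", {
  g1 <- make_gtin("570000000001")
  g2 <- make_gtin("570000000002")
  dbs <- list(
    gs1like = make_specific_db(g1, "milk skimmed 1l", 150, "gs1like"),
    chemlike = make_specific_db(c(g1, g2), c("milk skimmed", "soap"),
                                c(NA, NA), "chemlike"),
    offlike = make_specific_db(g2, "soap bar", 10, "offlike")
  )
  hit <- match_specific(c(g1, g2, make_gtin("570000000003")), dbs)
  expect_equal(hit$match_source,
               c("specific:gs1like", "specific:chemlike", NA))
  # risk score from chemlike survives the gs1like priority overwrite
  expect_equal(hit$risk_score[1], "B")
  # offlike nutrients merged where chemlike has none
  expect_equal(hit$energy_kj[2], 10)
})

test_that("pipeline order: digit filter, then GTIN, then generic", {
  g <- make_gtin("570000000007")
  pt <- as_purchase_table(tibble::tibble(
    participant_id = "p1", retailer_id = "r1",
    purchase_datetime = "2022-03-01T09:00:00",
    item_number = c(g, "12", "445566"),
    item_name = c("mystery product", "milk whole", "bread wholegrain"),
    unit_price_dkk = 10, quantity = 1L, discount_dkk = 0))
  dbs <- list(gs1like = make_specific_db(g, "milk skimmed 1l", 150))
  enr <- enrich(pt, make_generic_db(), dbs)
  m <- enr$matches[match(c(g, "12", "445566"), enr$matches$item_number_raw), ]
  # GTIN row matches specifically even though its receipt name is junk
  expect_equal(m$match_source[1], "specific:gs1like")
  # and its generic category comes from the database product name
  expect_equal(m$category_id[1], "milk_skimmed")
  # too-short item number is excluded from the GTIN route but its name
  # still matches generically
  expect_true(m$flag_excluded_item_number[2])
  expect_equal(m$match_source[2], "generic")
  expect_true(is.na(m$gtin[2]))
  expect_equal(m$match_source[3], "generic")
  expect_equal(m$category_id[3], "bread_wholegrain")
})

test_that("every unique product gets exactly one exclusive match outcome", {
  co <- generate_cohort(small_config())
  enr <- enrich(co$purchases, co$generic_db, co$specific_dbs)
  uniq <- dplyr::distinct(co$purchases, item_number, item_name)
  expect_equal(nrow(enr$matches), nrow(uniq))
  expect_true(all(enr$matches$match_source %in%
                    c("specific:gs1like", "specific:chemlike",
                      "specific:offlike", "generic", "unmatched")))
  # specific match implies a gtin
  spec <- startsWith(enr$matches$match_source, "specific")
  expect_true(all(!is.na(enr$matches$gtin[spec])))
  # excluded item numbers never carry a gtin
  expect_true(all(is.na(
    enr$matches$gtin[enr$matches$flag_excluded_item_number])))
  # summary counts partition the unique products
  s <- enr$summary
  expect_equal(s$n_specific_direct + s$n_generic + s$n_unmatched,
               s$n_unique_products)
})

test_that("enrich agrees with a brute-force exhaustive matcher", {
  co <- generate_cohort(small_config(n_products = 40, n_participants = 8,
                                     months = 3, name_noise_level = 0.3))
  cfg <- enrich_config()
  enr <- enrich(co$purchases, co$generic_db, co$specific_dbs, cfg)

  # test-local oracle: literal per-category re-scoring from the formula
  w <- c(type = 4, specific = 3, generic = 1, brand = 2, flavor = 1,
         fat = 1)
  brute_one <- function(clean, db) {
    scores <- sapply(seq_len(nrow(db)), function(i) {
      s <- 0
      for (k in names(w)) {
        pat <- db[[paste0("pattern_", k)]][i]
        if (!is.na(pat) && nzchar(pat) && grepl(pat, clean, perl = TRUE)) {
          s <- s + w[[k]]
        }
      }
      s
    })
    ord <- order(-scores, db$category_id)
    best <- ord[1]
    if (scores[best] < cfg$min_score) {
      return(list(cat = NA_character_, score = scores[best]))
    }
    list(cat = db$category_id[best], score = scores[best])
  }
  gen_rows <- enr$matches[enr$matches$match_source %in%
                            c("generic", "unmatched"), ]
  for (i in seq_len(nrow(gen_rows))) {
    clean <- preprocess_name(gen_rows$item_name_raw[i], cfg)$clean_name
    oracle <- brute_one(clean, co$generic_db)
    expect_identical(gen_rows$category_id[i], oracle$cat,
                     label = gen_rows$item_name_raw[i])
    expect_equal(gen_rows$score[i], oracle$score)
  }
})

test_that("classification accuracy degrades as name noise grows", {
  acc <- sapply(c(0, 0.4, 0.9), function(noise) {
    mean(sapply(1:3, function(seed) {
      co <- generate_cohort(small_config(
        name_noise_level = noise, seed = seed,
        specific_db_coverage = list(gs1like = 0, chemlike = 0,
                                    offlike = 0)))
      enr <- enrich(co$purchases, co$generic_db, co$specific_dbs)
      ev <- evaluate_matching(enr, co$truth$observed_products,
                              co$generic_db)
      # accuracy over all products, counting unmatched as failures
      ev$rates$exact_rate_unique *
        ev$rates$n_evaluated / nrow(enr$matches)
    }))
  })
  expect_true(all(diff(acc) < 0))
  expect_equal(acc[1], 1)
})

test_that("review queue holds flagged products, volume-descending", {
  co <- generate_cohort(small_config(name_noise_level = 0.4))
  enr <- enrich(co$purchases, co$generic_db, co$specific_dbs)
  q <- export_review_queue(enr)
  flagged <- enr$matches$flag_greedy | enr$matches$flag_ambiguous |
    enr$matches$match_source == "unmatched"
  expect_equal(nrow(q), sum(flagged))
  expect_true(all(diff(q$purchase_volume) <= 0))

  # no flags -> empty queue
  clean <- generate_cohort(small_config(name_noise_level = 0,
                                        internal_code_prob = 0))
  enr2 <- enrich(clean$purchases, clean$generic_db, clean$specific_dbs)
  expect_equal(nrow(export_review_queue(enr2)), 0)
})

test_that("enrichment output is deterministic across runs", {
  co <- generate_cohort(small_config())
  a <- enrich(co$purchases, co$generic_db, co$specific_dbs)
  b <- enrich(co$purchases, co$generic_db, co$specific_dbs)
  expect_identical(a$matches, b$matches)
  expect_identical(a$summary, b$summary)
})

test_that("tidy and glance expose the match table and summary", {
  pt <- as_purchase_table(make_receipts_df())
  enr <- enrich(pt, make_generic_db())
  expect_identical(tidy(enr), enr$matches)
  expect_identical(glance(enr), enr$summary)
  expect_equal(nrow(glance(enr)), 1)
})
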