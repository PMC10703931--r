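# The modified relative-difference statistic and nutrient concordance.

test_that("statistic matches its definition on direct cases", {
  expect_equal(modified_relative_difference(100, 100), 0)
  expect_equal(modified_relative_difference(0, 7), 1)
  expect_equal(modified_relative_difference(300, 400), 0.25)
  expect_equal(modified_relative_difference(0, 0), 0)  # convention
  expect_error(modified_relative_difference(-1, 2), "non-negative")
})

test_that("statistic is symmetric, bounded and scale-invariant", {
  set.seed(11)
  a <- runif(500, 0, 1000)
  b <- runif(500, 0, 1000)
  d <- modified_relative_difference(a, b)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, modified_relative_difference(b, a))
  for (k in c(0.001, 3, 1e6)) {
    expect_equal(modified_relative_difference(k * a, k * b), d)
  }
  expect_equal(modified_relative_difference(a, a), rep(0, 500))
})

test_that("doubly-matched products are compared, others counted out", {
  g1 <- make_gtin("570000000011")
  g2 <- make_gtin("570000000012")
  pt <- as_purchase_table(tibble::tibble(
    participant_id = "p1", retailer_id = "r1",
    purchase_datetime = "2022-01-01T10:00:00",
    item_number = c(g1, g2, "777777"),
    item_name = c("milk skimmed", "mystery", "bread wholegrain"),
    unit_price_dkk = 10, quantity = c(2L, 1L, 1L), discount_dkk = 0))
  dbs <- list(gs1like = make_specific_db(
    c(g1, g2), c("milk skimmed", "mystery"), c(120, 500)))
  enr <- enrich(pt, make_generic_db(), dbs)
  comp <- compare_nutrients(enr, make_generic_db(), dbs)
  # g2 has no generic category; the bread product has no gs1 record
  expect_setequal(unique(comp$gtin), g1)
  expect_equal(attr(comp, "n_excluded"), 2)
  got <- comp[comp$nutrient == "energy_kj", ]
  expect_equal(got$rel_diff,
               modified_relative_difference(150, 120))
  expect_equal(got$purchase_volume, 2)
})

test_that("zero generator noise gives zero differences everywhere", {
  co <- generate_cohort(small_config(nutrient_noise_sigma = 0,
                                     name_noise_level = 0))
  enr <- enrich(co$purchases, co$generic_db, co$specific_dbs)
  comp <- compare_nutrients(enr, co$generic_db, co$specific_dbs)
  expect_gt(nrow(comp), 0)
  expect_true(all(comp$rel_diff == 0))
})

test_that("CDF is a monotone step function reaching one", {
  comp <- tibble::tibble(
    nutrient = "energy_kj",
    rel_diff = c(0.2, 0.6),
    purchase_volume = c(9, 1)
  )
  un <- rel_diff_cdf(comp, "energy_kj", "unique")
  expect_equal(un$rel_diff, c(0.2, 0.6))
  expect_equal(un$cum_fraction, c(0.5, 1.0))
  vol <- rel_diff_cdf(comp, "energy_kj", "volume")
  expect_equal(vol$cum_fraction, c(0.9, 1.0))

  # degenerate: all zero differences -> single jump to 1 at 0
  allz <- rel_diff_cdf(tibble::tibble(nutrient = "energy_kj",
                                      rel_diff = c(0, 0, 0),
                                      purchase_volume = 1), "energy_kj")
  expect_equal(allz, tibble::tibble(rel_diff = 0, cum_fraction = 1))

  # empty input -> explicit empty result
  expect_equal(nrow(rel_diff_cdf(comp, "fat_g")), 0)

  co <- generate_cohort(small_config())
  enr <- enrich(co$purchases, co$generic_db, co$specific_dbs)
  comp2 <- compare_nutrients(enr, co$generic_db, co$specific_dbs)
  cdf <- rel_diff_cdf(comp2, "energy_kj")
  expect_true(all(diff(cdf$cum_fraction) > 0))
  expect_equal(cdf$cum_fraction[nrow(cdf)], 1)
})

test_that("group medians match a sort-based oracle", {
  comp <- tibble::tibble(
    nutrient = "energy_kj",
    category_id = c("a", "a", "a", "b"),
    rel_diff = c(0.1, 0.3, 0.5, 0.42),
    purchase_volume = 1
  )
  med <- group_medians(comp)
  expect_equal(med$median_rel_diff[med$category_id == "a"], 0.3)
  expect_equal(med$median_rel_diff[med$category_id == "b"], 0.42)
  # overall equals the sorted mid-point of the pooled values
  pooled <- sort(comp$rel_diff)
  expect_equal(med$median_rel_diff[med$category_id == "overall"],
               (pooled[2] + pooled[3]) / 2)

  co <- generate_cohort(small_config())
  enr <- enrich(co$purchases, co$generic_db, co$specific_dbs)
  comp2 <- compare_nutrients(enr, co$generic_db, co$specific_dbs)
  med2 <- group_medians(comp2, co$generic_db)
  v <- sort(comp2$rel_diff[comp2$nutrient == "energy_kj"])
  n <- length(v)
  oracle <- if (n %% 2) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  expect_equal(med2$median_rel_diff[med2$category_id == "overall"], oracle)
})
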