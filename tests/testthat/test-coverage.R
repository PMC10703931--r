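# Retailer-subset coverage analysis: profiles, differences, dispersion.

# tiny enriched-style line table for hand computation
make_cov_lines <- function() {
  tibble::tibble(
    participant_id = rep(c("p1", "p2"), c(6, 4)),
    retailer_id = c("A", "A", "A", "B", "B", "B", "A", "A", "B", "B"),
    food_group = c("bread", "bread", "milk", "milk", "milk", "tobacco",
                   "bread", "milk", "bread", "bread"),
    is_food = TRUE,
    quantity = 1L,
    unit_price_ore = 1000L,
    discount_ore = 0L
  )
}

test_that("retailers rank by line count with id tie-break", {
  lines <- tibble::tibble(
    retailer_id = c(rep("A", 10), rep("B", 5), rep("C", 5)))
  r <- rank_retailers(lines)
  expect_equal(r$retailer_id, c("A", "B", "C"))
  # permutation-invariant
  expect_equal(rank_retailers(lines[sample.int(20), ]), r)
})

test_that("top food groups counts cohort-wide and warns when short", {
  lines <- make_cov_lines()
  expect_warning(g <- top_food_groups(lines, 20), "3 food groups")
  expect_equal(g[1:2], c("bread", "milk"))
})

test_that("group proportions match a hand count on the fixture", {
  lines <- make_cov_lines()
  g <- c("bread", "milk", "tobacco")
  # p1 at retailer A: 2 bread, 1 milk of 3 lines
  p <- group_proportions(lines, "p1", "A", g)
  expect_equal(p$proportion, c(2 / 3, 1 / 3, 0))
  # p1 over all retailers: 2/6 bread, 3/6 milk, 1/6 tobacco
  p_all <- group_proportions(lines, "p1", c("A", "B"), g)
  expect_equal(p_all$proportion, c(2 / 6, 3 / 6, 1 / 6))
  # participant never visits subset retailer -> zero flag
  only_a <- dplyr::filter(lines, !(participant_id == "p2" &
                                     retailer_id == "B"))
  z <- group_proportions(only_a, "p2", "B", g)
  expect_true(all(z$zero_subset_flag))
  expect_true(all(is.na(z$proportion)))
  expect_error(group_proportions(lines, "p1", "Z", g), "unknown retailer")
})

test_that("subset equal to the full set gives exact zeros", {
  co <- generate_cohort(small_config())
  lines <- lines_with_truth(co)
  g <- suppressWarnings(top_food_groups(lines, 20))
  cov <- coverage_differences(
    lines, g, subsets = list(all = sort(unique(lines$retailer_id))))
  expect_true(all(cov$pp_difference == 0))
  expect_true(all(cov$rel_difference_pct[!is.na(cov$rel_difference_pct)]
                  == 0))
})

test_that("a group absent from the subset hits exactly -100%", {
  lines <- make_cov_lines()
  g <- c("bread", "milk", "tobacco")
  cov <- coverage_differences(lines, g, subsets = list(onlyA = "A"))
  tob <- dplyr::filter(cov, participant_id == "p1", group == "tobacco")
  expect_equal(tob$rel_difference_pct, -100)
  expect_true(all(cov$rel_difference_pct >= -100, na.rm = TRUE))
})

test_that("differences match brute-force enumeration on the fixture", {
  lines <- make_cov_lines()
  g <- c("bread", "milk", "tobacco")
  cov <- coverage_differences(lines, g, subsets = list(onlyA = "A"))
  # hand computation, p1: full = (1/3, 1/2, 1/6), A-only = (2/3, 1/3, 0)
  p1 <- dplyr::filter(cov, participant_id == "p1")
  expect_equal(p1$pp_difference[p1$group == "bread"],
               100 * (2 / 3 - 1 / 3))
  expect_equal(p1$pp_difference[p1$group == "milk"],
               100 * (1 / 3 - 1 / 2))
  expect_equal(p1$rel_difference_pct[p1$group == "milk"],
               100 * (1 / 3 - 1 / 2) / (1 / 2))
  # p2: full = (3/4, 1/4, 0), A-only = (1/2, 1/2, 0)
  p2 <- dplyr::filter(cov, participant_id == "p2")
  expect_equal(p2$pp_difference[p2$group == "bread"],
               100 * (1 / 2 - 3 / 4))
  # tobacco p_full = 0 -> relative difference undefined, pp defined
  expect_true(is.na(p2$rel_difference_pct[p2$group == "tobacco"]))
  expect_equal(p2$pp_difference[p2$group == "tobacco"], 0)
})

test_that("quantity weighting counts units, not lines", {
  lines <- make_cov_lines()
  lines$quantity[1] <- 4L  # p1, retailer A, bread
  g <- c("bread", "milk")
  p <- group_proportions(lines, "p1", "A", g, weight = "quantity")
  expect_equal(p$proportion, c(5 / 6, 1 / 6))
  p_lines <- group_proportions(lines, "p1", "A", g, weight = "lines")
  expect_equal(p_lines$proportion, c(2 / 3, 1 / 3))
})

test_that("dispersion is zero at the full set, NA for one participant", {
  lines <- make_cov_lines()
  g <- c("bread", "milk")
  cov <- coverage_differences(lines, g,
                              subsets = list(all = c("A", "B")))
  d <- dispersion_summary(cov)
  expect_true(all(d$sd_pp == 0))

  solo <- dplyr::filter(lines, participant_id == "p1")
  cov1 <- coverage_differences(solo, g, subsets = list(onlyA = "A"))
  d1 <- dispersion_summary(cov1)
  expect_true(all(is.na(d1$sd_pp[d1$group != "(pooled)"])))
})

test_that("percentiles match a sort-based oracle", {
  # all-zero differences -> all percentiles zero
  lines <- make_cov_lines()
  cov0 <- coverage_differences(lines, c("bread", "milk"),
                               subsets = list(all = c("A", "B")))
  p0 <- percentile_summary(cov0)
  expect_equal(unlist(p0[, c("p10", "p50", "p90")]),
               c(p10 = 0, p50 = 0, p90 = 0))

  # median of {-100, 0, 100} is 0
  fake <- tibble::tibble(
    participant_id = as.character(1:3), subset_id = "s",
    subset_type = "individual", subset_size = 1, group = "g",
    p_subset = 0, p_full = 1, pp_difference = 0,
    rel_difference_pct = c(-100, 0, 100), zero_subset_flag = FALSE)
  expect_equal(percentile_summary(fake)$p50, 0)

  # 25-value fixture against sort-based linear interpolation
  set.seed(9)
  vals <- round(runif(25, -100, 100), 1)
  fake25 <- fake[rep(1, 25), ]
  fake25$participant_id <- as.character(1:25)
  fake25$rel_difference_pct <- vals
  got <- percentile_summary(fake25, c(10, 50, 90))
  s <- sort(vals)
  interp <- function(p) {
    h <- (25 - 1) * p + 1
    s[floor(h)] + (h - floor(h)) * (s[ceiling(h)] - s[floor(h)])
  }
  expect_equal(c(got$p10, got$p50, got$p90),
               c(interp(0.1), interp(0.5), interp(0.9)))
})

test_that("tobacco sold at a disjoint retailer reads as non-use", {
  # participant buys cigarettes only at retailer B; evaluated on A alone
  # the tobacco-like group drops out entirely (-100%)
  lines <- tibble::tibble(
    participant_id = "p1",
    retailer_id = c("A", "A", "A", "B"),
    food_group = c("bread", "milk", "bread", "tobacco"),
    is_food = c(TRUE, TRUE, TRUE, FALSE),
    quantity = 1L, unit_price_ore = 1000L, discount_ore = 0L)
  cov <- coverage_differences(lines, c("bread", "milk", "tobacco"),
                              subsets = list(onlyA = "A"))
  tob <- dplyr::filter(cov, group == "tobacco")
  expect_equal(tob$p_full, 1 / 4)
  expect_equal(tob$p_subset, 0)
  expect_equal(tob$rel_difference_pct, -100)
})
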