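test_that("delay is defined only for level 1/2 transfers and is strict at 60", {
  expect_true(is_delayed("LEVEL1", 75))
  expect_false(is_delayed("LEVEL2", 60.0))  # "exceeding" is strict
  expect_true(is.na(is_delayed("NTC", 90)))
  expect_true(is.na(is_delayed("LEVEL1", NA)))  # missing time: not applicable
  expect_equal(is_delayed(c("LEVEL1", "LEVEL3"), c(61, 61)), c(TRUE, NA))
})

test_that("undertriage needs red criteria, a reachable band and the destination set", {
  b <- function(x) factor(x, levels = c("B15", "B30", "B45", "B60", "BEYOND"))
  expect_true(is_undertriaged("RED", "NTC", b("B30")))
  expect_true(is.na(is_undertriaged("NOT_RED", "NTC", b("B30"))))
  expect_false(is_undertriaged("RED", "NTC", b("BEYOND")))
  expect_false(is_undertriaged("RED", "LEVEL3", b("B15")))
  expect_true(is_undertriaged("RED", "LEVEL3", b("B15"), strict = TRUE))
  expect_error(is_undertriaged("RED", "NTC", NA), "band map")
})

test_that("strict undertriage counts at least as many as the default", {
  assessed <- make_random_assessed(n = 600, seed = 11)
  strict <- is_undertriaged(assessed$triage_class, assessed$destination_level,
                            assessed$band, strict = TRUE)
  expect_gte(sum(strict, na.rm = TRUE),
             sum(assessed$undertriaged, na.rm = TRUE))
  # flag implications hold record-wise
  expect_true(all(assessed$triage_class[which(assessed$undertriaged)] == "RED"))
  expect_true(all(assessed$destination_level[which(assessed$delayed)] %in%
                    c("LEVEL1", "LEVEL2")))
})

test_that("cohort table equals a base-R group-by oracle on random data", {
  assessed <- make_random_assessed(n = 800, seed = 21)
  tab <- build_cohort_table(assessed)
  red <- assessed$triage_class == "RED"

  # independent tallies with base table()
  for (rg in c("EAST", "NORTH", "MIDDLE")) {
    row <- tab[tab$section == "region" & tab$level == rg, ]
    expect_equal(row$n_all, sum(assessed$region == rg))
    expect_equal(row$n_red, sum(assessed$region == rg & red))
  }
  mvc <- tab[tab$section == "mechanism_blunt" & tab$level == "MVC", ]
  expect_equal(mvc$n_all, sum(assessed$mechanism_code == "MVC"))
  # percentages recompute from counts (one-decimal, half-up)
  blunt_n <- sum(assessed$category == "BLUNT")
  expect_equal(mvc$pct_all, floor(100 * mvc$n_all / blunt_n * 10 + 0.5) / 10)
  # category counts partition the cohort
  mech <- tab[tab$section == "mechanism", ]
  expect_equal(sum(mech$n_all), nrow(assessed))
  expect_equal(sum(mech$n_red), sum(red))
})

test_that("access table equals a brute-force cross-tabulation", {
  assessed <- make_random_assessed(n = 1000, seed = 31)
  tab <- build_access_table(assessed)
  rc <- assessed[assessed$triage_class == "RED", ]
  tr <- rc[rc$destination_level %in% c("LEVEL1", "LEVEL2"), ]

  overall <- tab[tab$region == "OVERALL", ]
  expect_equal(overall$n, nrow(tr))
  expect_equal(overall$delayed_n, sum(tr$delayed, na.rm = TRUE))

  xt <- table(as.character(tr$region), as.character(tr$band))
  for (i in which(tab$region != "OVERALL" & tab$band != "TOTAL")) {
    expect_equal(tab$n[i], unname(xt[tab$region[i], tab$band[i]]))
  }
  # region totals sum to the citywide total
  expect_equal(sum(tab$n[tab$band == "TOTAL" & tab$region != "OVERALL"]),
               overall$n)
  expect_equal(sum(tab$delayed_n[tab$band == "TOTAL" & tab$region != "OVERALL"]),
               overall$delayed_n)
})

test_that("zero-transfer regions produce no division errors", {
  assessed <- make_random_assessed(n = 60, seed = 41)
  assessed$destination_level[assessed$region == "WEST"] <- factor("NTC",
    levels = levels(assessed$destination_level))
  tab <- build_access_table(assessed)
  expect_false(any(is.infinite(tab$n_pct)))
  expect_false(any(is.nan(unlist(tab[, c("n_pct", "delayed_pct")]))))
})

test_that("dispatch table ratios are direct and band ranges bracket them", {
  assessed <- make_random_assessed(n = 900, seed = 51)
  tab <- build_dispatch_table(assessed)
  rc <- assessed[assessed$triage_class == "RED", ]
  one <- tab[1, ]
  sub <- rc[rc$dispatch_center_id == one$dispatch_id, ]
  expect_equal(one$rc_n, nrow(sub))
  expect_equal(one$ntc_n, sum(sub$destination_level == "NTC"))
  if (one$l12_n > 0) {
    expect_equal(one$delayed_pct,
                 floor(1000 * one$delayed_n / one$l12_n + 0.5) / 10)
  }
  rng <- dispatch_band_range(tab)
  for (b in rng$band) {
    vals <- tab$delayed_pct[tab$band == b]
    if (any(!is.na(vals))) {
      expect_equal(rng$delayed_min[rng$band == b], min(vals, na.rm = TRUE))
      expect_equal(rng$delayed_max[rng$band == b], max(vals, na.rm = TRUE))
    }
  }
})

test_that("dispatch percentages match hand ratios", {
  b <- factor("B15", levels = c("B15", "B30", "B45", "B60", "BEYOND"))
  assessed <- tibble::tibble(
    dispatch_center_id = "D1",
    region = "EAST",
    band = b,
    triage_class = "RED",
    destination_level = factor(c(rep("LEVEL1", 10), rep("NTC", 5)),
                               levels = c("LEVEL1", "LEVEL2", "LEVEL3",
                                          "NTC", "MISSING")),
    delayed = c(rep(TRUE, 3), rep(FALSE, 7), rep(NA, 5)),
    undertriaged = c(rep(NA, 10), rep(TRUE, 5))
  )
  tab <- build_dispatch_table(assessed)
  expect_equal(tab$delayed_pct, 30.0)  # 3 of 10 level 1/2 transfers
  expect_equal(tab$ntc_pct, floor(1000 * 5 / 15 + 0.5) / 10)
})

test_that("cohort fixture reproduces the published demographic percentages", {
  fx <- make_cohort_fixture()
  assessed <- assess_records(fx$records, fx$band_map, fx$facilities)
  expect_equal(sum(assessed$triage_class == "RED"), 31072)
  tab <- build_cohort_table(assessed)
  g <- function(section, level) tab[tab$section == section & tab$level == level, ]

  expect_equal(g("sex", "MALE")$n_all, 75973)
  expect_equal(g("sex", "MALE")$pct_all, 73.8)
  expect_equal(g("sex", "FEMALE")$pct_all, 25.4)
  expect_equal(g("sex", "MALE")$pct_red, 66.3)
  expect_equal(g("age_group", "14-64")$pct_all, 87.9)
  expect_equal(g("age_group", "GE65")$pct_red, 28.2)
  expect_equal(g("mechanism", "BLUNT")$pct_all, 68.3)
  expect_equal(g("mechanism", "PENETRATING")$pct_all, 21.1)
  expect_equal(g("mechanism", "PENETRATING")$pct_red, 69.7)
  expect_equal(g("mechanism", "BLUNT")$pct_red, 11.2)
  expect_equal(g("mechanism_blunt", "MVC")$pct_all, 70.1)
  expect_equal(g("mechanism_blunt", "FALL")$pct_all, 29.9)
  expect_equal(g("mechanism_blunt", "MVC")$pct_red, 56.8)
  expect_equal(g("region", "EAST")$pct_all, 41.5)
  expect_equal(g("region", "EAST")$pct_red, 42.7)
  expect_equal(g("destination", "LEVEL1")$n_all + g("destination", "LEVEL2")$n_all,
               64300)
  expect_equal(g("destination", "NTC")$pct_red, 28.7)
})

test_that("access fixture reproduces the published region-by-band table", {
  fx <- make_access_fixture()
  assessed <- assess_records(fx$records, fx$band_map, fx$facilities)
  tab <- build_access_table(assessed)
  g <- function(region, band) tab[tab$region == region & tab$band == band, ]

  expect_equal(g("OVERALL", "TOTAL")$n, 20747)
  expect_equal(g("OVERALL", "TOTAL")$n_pct, 66.8)
  expect_equal(g("OVERALL", "TOTAL")$delayed_n, 4379)
  expect_equal(g("OVERALL", "TOTAL")$delayed_pct, 21.1)
  expect_equal(g("EAST", "TOTAL")$n_pct, 44.7)
  expect_equal(g("EAST", "TOTAL")$delayed_pct, 41.7)
  expect_equal(g("EAST", "B30")$n_pct, 67.3)
  expect_equal(g("EAST", "B30")$delayed_pct, 63.0)
  expect_equal(g("NORTH", "B30")$n_pct, 81.3)
  expect_equal(g("NORTH", "B60")$delayed_pct, 1.6)
  expect_equal(g("WEST", "B15")$delayed_pct, 41.2)
  expect_equal(g("SOUTH", "B15")$n_pct, 80.2)
  expect_equal(g("MIDDLE", "B15")$delayed_pct, 70.8)
})
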