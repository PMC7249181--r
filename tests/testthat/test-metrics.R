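test_that("phase totals bucket every dose and conserve water", {
  cal <- pheno_calendar()
  empty <- phase_totals(data.frame(point_id = character(0), date = as.Date(character(0)),
    depth = numeric(0)), cal)
  expect_equal(nrow(empty), 0)
  one <- phase_totals(
    data.frame(point_id = "P", date = as.Date("2016-08-10"), depth = 5), cal
  )
  expect_equal(one$phase_II, 5)
  expect_equal(one$phase_I + one$phase_III, 0)
  # random ledger vs brute-force filtered sums
  set.seed(14)
  d <- data.frame(
    point_id = sample(c("A", "B"), 80, TRUE),
    date = as.Date("2016-01-01") + sample(0:360, 80, TRUE),
    depth = runif(80, 0, 8)
  )
  pt <- phase_totals(d, cal)
  for (p in c("A", "B")) {
    s <- d[d$point_id == p, ]
    ph <- phase_of(s$date, cal)
    expect_equal(pt$phase_II[pt$point_id == p], sum(s$depth[ph == "II"]))
    expect_equal(pt$phase_I[pt$point_id == p], sum(s$depth[ph == "I"]))
    # conservation across all buckets
    row <- pt[pt$point_id == p, ]
    expect_equal(
      row$phase_I + row$phase_II + row$phase_III + row$pre_season + row$post_season,
      sum(s$depth)
    )
  }
})

test_that("water productivity follows the kg/ha-per-mm table convention", {
  expect_equal(water_productivity(5490, 232), 23.66, tolerance = 0.005)
  expect_equal(water_productivity(3468, 410), 8.46, tolerance = 0.005)
  expect_equal(water_productivity(0, 100), 0)
  expect_error(water_productivity(100, 0), "irrigation")
  # scale consistency
  expect_equal(water_productivity(2 * 5490, 2 * 232), water_productivity(5490, 232))
})

test_that("supply ratio is the percent closure of demand", {
  expect_equal(supply_ratio(0, 0, 500), 0)
  expect_equal(supply_ratio(860.6 - 300, 300, 860.6), 100)
  expect_error(supply_ratio(10, 10, 0), "etc_total")
})

test_that("maturity index is the weighted color-class mean with harvest trigger", {
  expect_equal(maturity_index(c(100, 0, 0, 0, 0, 0, 0, 0))$mi, 0)
  expect_equal(maturity_index(c(0, 0, 0, 0, 0, 0, 0, 100))$mi, 7)
  m <- maturity_index(c(0, 25, 25, 25, 25, 0, 0, 0))
  expect_equal(m$mi, 2.5)
  expect_true(m$harvest)
  expect_error(maturity_index(rep(0, 8)), "empty")
  expect_error(maturity_index(rep(1, 5)), "8")
})

test_that("planting density closes the rectangular spacing arithmetic", {
  expect_equal(planting_density(4, 1.35), 1851.85, tolerance = 0.01)
  expect_error(planting_density(0, 1), "spacings")
})

test_that("AIS-vs-NAIS savings come out of a phase-totals table", {
  toy <- data.frame(
    year = 2016, point_id = c("1", "2", "CR1", "CR2"),
    scheduling = c("NAIS", "NAIS", "AIS", "AIS"),
    phase_I = c(60, 80, 60, 80), phase_II = c(100, 100, 80, 80),
    phase_III = c(40, 40, 40, 40), total = c(200, 220, 180, 200)
  )
  s <- ais_water_saving(toy, 2016)
  expect_equal(unname(s["phase_II"]), 20)
  expect_equal(unname(s["phase_I"]), 0)
  expect_equal(unname(s["total"]), 100 * (210 - 190) / 210)
  expect_error(ais_water_saving(toy, 2014), "2014")
})

test_that("Duncan letters match the hand-executed range-table procedure", {
  fx <- duncan_fixture()
  res <- anova_duncan(fx$values, fx$groups)
  expect_lt(res$p_value, 0.05)
  got <- setNames(res$table$letters, res$table$group)
  expect_equal(got[names(fx$expected)], fx$expected)
})

test_that("Duncan degenerate and boundary behaviors", {
  # identical groups: one shared letter
  same <- anova_duncan(rep(c(5, 6, 7), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(same$table$letters == "a"))
  # two clearly separated groups: distinct letters
  two <- anova_duncan(c(1, 1.1, 0.9, 5, 5.2, 4.8), rep(c("lo", "hi"), each = 3))
  expect_equal(sort(unique(two$table$letters)), c("a", "b"))
  # zero within-group variance with unequal means: exact separation + warning
  expect_warning(
    zw <- anova_duncan(rep(c(1, 2, 3), each = 3), rep(c("x", "y", "z"), each = 3)),
    "zero within-group"
  )
  expect_equal(length(unique(zw$table$letters)), 3)
  expect_error(anova_duncan(1:4, rep("a", 4)), "2 groups")
  expect_error(anova_duncan(1:3, c("a", "a", "b")), "replicates")
})

test_that("letter displays are transitive-consistent on random data", {
  set.seed(31)
  for (i in 1:15) {
    k <- sample(3:6, 1)
    mus <- sort(runif(k, 0, 6))
    vals <- unlist(lapply(mus, function(m) rnorm(5, m, 0.8)))
    res <- anova_duncan(vals, rep(letters[1:k], each = 5))
    tab <- res$table # sorted by decreasing mean
    shares <- function(i, j) {
      any(strsplit(tab$letters[i], "")[[1]] %in% strsplit(tab$letters[j], "")[[1]])
    }
    for (a in 1:(nrow(tab) - 1)) {
      for (b in (a + 1):nrow(tab)) {
        if (shares(a, b)) {
          # interval property: everything between shares a letter with both
          for (m in a:b) expect_true(shares(a, m) && shares(m, b))
        }
      }
    }
  }
})
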