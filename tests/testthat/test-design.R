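# Design construction: seasons, strata, referent selection, row assembly,
# centering, collinearity screen.

test_that("season boundaries follow the burden-based definitions", {
  expect_equal(as.character(assign_season(as.Date("2010-08-19"))), "summer")
  expect_equal(as.character(assign_season(as.Date("2010-08-20"))), "fall")
  expect_equal(as.character(assign_season(as.Date("2010-01-01"))), "winter")
  expect_equal(as.character(assign_season(as.Date("2008-02-29"))), "winter")
  expect_equal(as.character(assign_season(as.Date("2010-03-01"))), "spring")
  expect_equal(as.character(assign_season(as.Date("2010-05-31"))), "spring")
  expect_equal(as.character(assign_season(as.Date("2010-06-01"))), "summer")
  expect_equal(as.character(assign_season(as.Date("2010-12-31"))), "fall")
  # the four seasons partition every calendar day
  days <- seq(as.Date("2008-01-01"), as.Date("2008-12-31"), by = "day")
  expect_false(anyNA(assign_season(days)))
})

test_that("the year-month-weekday index spans exactly 840 strata", {
  days <- seq(as.Date("2005-01-01"), as.Date("2014-12-31"), by = "day")
  idx <- stratum_index(days)
  expect_equal(length(unique(idx)), 840L)
  expect_true(all(idx >= 1 & idx <= 840))
  # same (year, month, weekday) -> same stratum; different year -> different
  expect_equal(stratum_index(as.Date("2010-02-09")),
               stratum_index(as.Date("2010-02-16")))
  expect_false(stratum_index(as.Date("2010-02-09")) ==
               stratum_index(as.Date("2011-02-08")))
  expect_error(stratum_index(as.Date("2004-12-31")), "outside")
})

test_that("every stratum holds at most 5 dates over the full calendar", {
  days <- seq(as.Date("2005-01-01"), as.Date("2014-12-31"), by = "day")
  counts <- table(stratum_index(days))
  expect_true(all(counts >= 4 & counts <= 5))
})

test_that("referents match the worked February 2010 example exactly", {
  refs <- select_referents(as.Date("2010-02-09"))  # second Tuesday
  expect_equal(refs, as.Date(c("2010-02-02", "2010-02-16", "2010-02-23")))
})

test_that("months with five matching weekdays yield three sampled referents", {
  # March 2010 has five Mondays: 1, 8, 15, 22, 29
  case <- as.Date("2010-03-08")
  refs <- select_referents(case, seed = 42)
  expect_length(refs, 3)
  expect_true(all(refs %in% brute_force_referents(case)))
  expect_false(case %in% refs)
  expect_identical(refs, select_referents(case, seed = 42))  # seeded contract
  other <- select_referents(case, seed = 43)
  expect_true(all(other %in% brute_force_referents(case)))
})

test_that("referent invariants hold across a year of case dates", {
  days <- seq(as.Date("2010-01-01"), as.Date("2010-12-31"), by = "day")
  set.seed(1)
  for (d in sample(days, 60)) {
    d <- as.Date(d)
    refs <- select_referents(d)
    expect_true(length(refs) <= 3)
    expect_false(d %in% refs)
    expect_true(all(format(refs, "%Y-%m") == format(d, "%Y-%m")))
    expect_true(all(format(refs, "%u") == format(d, "%u")))
    expect_equal(unique(stratum_index(c(d, refs), 2010)),
                 stratum_index(d, 2010))
  }
})

test_that("build_rows produces one case plus referents with shared stratum", {
  ts <- tiny_series(90, "2010-01-01")
  v <- visits_on(c("2010-01-20", "2010-02-09", "2010-03-10"),
                 c("A", "B", "A"))
  rows <- build_rows(v, ts, covariates = c("nox", "temp"), seed = 7)
  expect_s3_class(rows, "cco_rows")
  for (id in unique(rows$visit_id)) {
    sub <- rows[rows$visit_id == id, ]
    expect_equal(sum(sub$y), 1L)
    expect_true(nrow(sub) - 1L <= 3L)
    expect_equal(length(unique(sub$stratum)), 1L)
    expect_equal(length(unique(as.character(sub$season))), 1L)
  }
  # tract-1 nox is the day index, so each window's 3DMA is day - 1
  case <- rows[rows$visit_id == "v001" & rows$y == 1, ]
  expect_equal(case$nox, as.numeric(case$window_date - as.Date("2010-01-01")))
})

test_that("row counts match brute-force enumeration on a toy calendar", {
  ts <- tiny_series(59, "2010-01-01")  # Jan + Feb 2010
  # February dates only: every candidate window has a complete 3DMA, so the
  # count is fully determined by the calendar
  dates <- seq(as.Date("2010-02-01"), as.Date("2010-02-25"), by = "day")
  v <- visits_on(dates, c("A", "B"))
  rows <- build_rows(v, ts, covariates = c("nox", "temp"), seed = 3)
  expected <- sum(vapply(dates, function(d) {
    cand <- brute_force_referents(as.Date(d))
    1L + min(3L, length(cand))
  }, integer(1)))
  expect_equal(nrow(rows), expected)
  # each weekday occurs exactly 4 times in Feb 2010: 4 rows per visit
  expect_equal(nrow(rows), 4L * nrow(v))
})

test_that("visits whose case window is incomplete are dropped and logged", {
  ts <- tiny_series(40, "2010-01-01")
  v <- visits_on(c("2010-01-02", "2010-01-20"))  # first lacks lag 2
  rows <- build_rows(v, ts, covariates = "nox", seed = 1)
  expect_false("v001" %in% rows$visit_id)
  expect_equal(attr(rows, "n_dropped_visits"), 1L)
  expect_true("v002" %in% rows$visit_id)
})

test_that("constant exposures give identical case and referent covariates", {
  dates <- seq(as.Date("2010-01-01"), as.Date("2010-06-30"), by = "day")
  ts <- tract_series("A", cbind(0, 0), dates,
                     list(nox = matrix(8.5, 1, length(dates))))
  v <- visits_on(c("2010-02-10", "2010-04-15", "2010-05-20"))
  rows <- build_rows(v, ts, covariates = "nox", seed = 2)
  expect_true(all(rows$nox == 8.5))
})

test_that("centering zeroes means, is idempotent, and builds the interaction", {
  ts <- tiny_series(90)
  v <- visits_on(c("2010-01-20", "2010-02-09", "2010-03-10"), c("A", "B", "A"))
  rows <- build_rows(v, ts, covariates = c("nox", "temp"), seed = 7)
  # give temp some variation so the interaction is nontrivial
  rows$dewp <- rows$nox / 3
  attr(rows, "covariates") <- c("nox", "temp", "dewp")
  cen <- center_covariates(rows)
  for (v2 in c("nox", "temp", "dewp", "temp_dewp")) {
    expect_lt(abs(mean(cen[[v2]])), 1e-10)
  }
  means <- attr(cen, "centering_means")
  expect_equal(unname(means["nox"]), mean(rows$nox))
  twice <- center_covariates(cen)
  expect_equal(twice$nox, cen$nox)
  expect_equal(twice$temp_dewp, cen$temp_dewp)
  one <- center_covariates(rows[1, , drop = FALSE], c("nox", "temp"))
  expect_equal(one$nox, 0)
})

test_that("collinearity screen drops duplicates and respects priority", {
  set.seed(5)
  n <- 2000
  df <- data.frame(a = rnorm(n))
  df$b <- df$a                      # perfect duplicate
  expect_warning(scr <- collinearity_screen(df, covariates = c("a", "b")),
                 "retaining one")
  expect_length(scr$retained, 1L)

  # independent white noise is fully retained
  df2 <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(df2) <- c("v1", "v2", "v3", "v4", "v5")
  scr2 <- collinearity_screen(df2, covariates = names(df2))
  expect_equal(sort(scr2$retained), sort(names(df2)))
  # agrees with the directly computed correlation matrix
  expect_true(max(abs(cor(df2)[upper.tri(diag(5))])) <= 0.9)

  # CO built as NOx plus small noise: CO removed, NOx retained
  df3 <- data.frame(nox = rnorm(n, 12, 5))
  df3$co <- 0.1 + 0.02 * df3$nox + rnorm(n, 0, 0.01)
  df3$o3 <- rnorm(n)
  scr3 <- collinearity_screen(df3, covariates = c("nox", "co", "o3"))
  expect_true("co" %in% scr3$removed)
  expect_true(all(c("nox", "o3") %in% scr3$retained))
  expect_equal(scr3$log$against[1], "nox")

  # all mutually collinear: one survivor, with a warning
  df4 <- data.frame(x = rnorm(n))
  df4$y <- 2 * df4$x; df4$z <- -df4$x
  expect_warning(scr4 <- collinearity_screen(df4, covariates = c("x", "y", "z")),
                 "retaining one")
  expect_length(scr4$retained, 1L)
})

test_that("default pipeline screening mirrors the conventional removals", {
  cfg <- sim_config(n_tracts = 15, seed = 6, target_total_visits = 1500,
                    date_range = as.Date(c("2005-01-01", "2006-12-31")))
  ex <- generate_exposures(cfg)
  v <- generate_visits(ex, cfg)
  rows <- build_rows(v, ex, seed = 6)
  scr <- collinearity_screen(rows)
  expect_true("co" %in% scr$removed)      # collinear with nox
  expect_true("nox" %in% scr$retained)
  expect_true("dewp" %in% scr$removed)    # collinear with temp
  expect_true("temp" %in% scr$retained)
})

test_that("season subsetting preserves row attributes", {
  ts <- tiny_series(200)
  v <- visits_on(c("2010-02-10", "2010-04-15", "2010-06-20"), "A")
  rows <- build_rows(v, ts, covariates = "nox", seed = 1)
  sp <- season_rows(rows, "spring")
  expect_true(all(sp$season == "spring"))
  expect_equal(attr(sp, "covariates"), "nox")
})

test_that("case-crossover tables round-trip with their JSON sidecar", {
  ts <- tiny_series(90)
  v <- visits_on(c("2010-01-20", "2010-02-09"), "A")
  rows <- center_covariates(build_rows(v, ts, covariates = c("nox", "temp"),
                                       seed = 4))
  path <- tempfile(fileext = ".csv")
  write_rows(rows, path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$seed, 4L)
  expect_equal(unlist(side$covariates), c("nox", "temp"))
  expect_equal(side$centering_means$nox,
               unname(attr(rows, "centering_means")["nox"]))
  unlink(c(path, paste0(path, ".json")))
})
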