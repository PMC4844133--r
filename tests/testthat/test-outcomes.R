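test_that("biennial polity panel samples every other year", {
  tab <- country_year_table(
    country = rep(c("A", "B"), each = 4),
    year = rep(c(1898, 1899, 1900, 2012), 2),
    value = c(5, 6, 7, 8, -66, -77, -88, 3))
  p <- biennial_polity(tab)
  expect_equal(ncol(p$values), 58)  # 1898, 1900, ..., 2012
  expect_equal(p$values["A", "1898"], 5)
  expect_true(is.na(p$values["A", "1902"]))
  expect_equal(p$values["A", "2012"], 8)
  # odd years are not sampled
  expect_false("1899" %in% colnames(p$values))
  # special codes -66/-77/-88 become missing
  expect_true(is.na(p$values["B", "1898"]))
  expect_true(is.na(p$values["B", "1900"]))
  expect_equal(p$values["B", "2012"], 3)
  # a country with no records is all-missing
  p2 <- biennial_polity(tab, countries = c("A", "B", "C"))
  expect_true(all(is.na(p2$values["C", ])))
  expect_error(biennial_polity(tab, start = 2000, end = 1990), "start")
})

test_that("panel differencing drops one bin and subtracts adjacent bins", {
  vals <- rbind(A = c(-7, -5, -5, 3), B = c(2, NA, 4, 4))
  p <- panel_outcome(vals, c(1898, 1900, 1902, 1904), 2, "polity_state")
  d <- panel_change(p)
  expect_equal(ncol(d$values), 3)
  expect_equal(d$variable, "polity_change")
  expect_equal(d$values["A", ], c("1900" = 2, "1902" = 0, "1904" = 8))
  # missing on either side propagates
  expect_true(all(is.na(d$values["B", c("1900", "1902")])))
  expect_equal(unname(d$values["B", "1904"]), 0)
  # constant series -> all-zero changes
  pc <- panel_outcome(rbind(A = rep(4, 5), B = rep(-2, 5)),
                      2000:2004, 1, "polity_state")
  expect_true(all(panel_change(pc)$values == 0))
  expect_error(panel_change(panel_outcome(cbind(A = 1), 2000, 1,
                                          "polity_state")), "2 bins")
})

test_that("differencing a cumulative panel recovers the increments", {
  set.seed(4)
  inc <- matrix(rpois(5 * 6, 1), 5, 6,
                dimnames = list(paste0("c", 1:5), NULL))
  cum <- t(apply(inc, 1, cumsum))
  p <- panel_outcome(cum, 1899 + 5 * (0:5), 5, "default_count")
  d <- panel_change(p)
  expect_equal(unname(d$values), unname(inc[, -1]))
  # telescoping: change sums to last minus first per country
  expect_equal(rowSums(d$values), cum[, 6] - cum[, 1])
})

test_that("default binning sums both creditor streams into 5-year bins", {
  fo <- country_year_table(c("A", "A"), c(1900, 1902), c(1, 1))
  do_ <- country_year_table("B", 1903, 1)
  p <- bin_defaults(fo, do_, start = 1899, width = 5)
  expect_equal(unname(p$values["A", "1899"]), 2)  # 1900 and 1902 in 1899-1903
  expect_equal(unname(p$values["B", "1899"]), 1)
  # boundary years 1903 vs 1904 split across consecutive bins
  fo2 <- country_year_table(c("A", "A"), c(1903, 1904), c(1, 1))
  do2 <- country_year_table(character(0), integer(0), numeric(0))
  p2 <- bin_defaults(fo2, do2, start = 1899, width = 5)
  expect_equal(unname(p2$values["A", c("1899", "1904")]), c(1, 1))
  # no events -> zero panel over the requested grid
  p3 <- bin_defaults(do2, do2, start = 1899, width = 5, end = 1913,
                     countries = "A")
  expect_true(all(p3$values == 0))
  expect_equal(ncol(p3$values), 3)
})

test_that("default counts are conserved and independent of sub-binning", {
  w <- tiny_world(seed = 10)
  dl <- make_default_like_panel(w, n_bins = 8, event_rate = 0.2, seed = 5)
  total_events <- sum(dl$foreign$value) + sum(dl$domestic$value)
  expect_equal(sum(dl$panel$values), total_events)
  # width-1 binning aggregated by 5 equals direct width-5 binning
  p1 <- bin_defaults(dl$foreign, dl$domestic, start = 1899, width = 1,
                     end = 1938, countries = w$nodes$ids)
  agg <- sapply(seq(1, 40, by = 5), function(j)
    rowSums(p1$values[, j:(j + 4), drop = FALSE]))
  expect_equal(unname(agg), unname(dl$panel$values))
})

test_that("bin alignment drops missing countries and subsets weights", {
  w <- tiny_world(seed = 11)
  ids <- w$nodes$ids
  vals <- matrix(rnorm(length(ids) * 3), length(ids), 3,
                 dimnames = list(ids, NULL))
  vals[1, 2] <- NA
  vals[, 3] <- NA
  p <- panel_outcome(pmin(pmax(vals, -10), 10), c(1898, 1900, 1902), 2,
                     "polity_state")
  al1 <- align_bin(p, 1, w$weights)
  expect_equal(al1$nodes, ids)
  al2 <- align_bin(p, 2, w$weights)
  expect_equal(length(al2$y), length(ids) - 1)
  expect_equal(dim(al2$weights[[1]]), rep(length(ids) - 1, 2))
  expect_false(ids[1] %in% al2$nodes)
  expect_error(align_bin(p, 3, w$weights), "fewer than 3")
  expect_error(align_bin(p, 9, w$weights), "no such bin")
})

test_that("grid and long-format readers round-trip panels", {
  # default grid dialect: country rows x year columns of 0/1 flags
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("country,1900,1901,1902",
               "A,1,0,1",
               "B,0,0,0",
               "C,0,1,0"), f)
  tab <- read_default_grid_csv(f)
  expect_equal(nrow(tab), 3)
  expect_equal(sort(tab$country), c("A", "A", "C"))
  expect_equal(tab$year[tab$country == "C"], 1901)
  # polity long dialect
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ccode,year,polity", "A,1900,5", "A,1902,6", "B,1900,-3"), f2)
  tab2 <- read_polity_csv(f2, cols = c(country = "ccode", year = "year",
                                       value = "polity"))
  expect_equal(tab2$value[tab2$country == "B"], -3)
  # panel writer
  p <- panel_outcome(rbind(A = c(1, 2), B = c(0, 1)), c(1899, 1904), 5,
                     "default_count")
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_panel_csv(p, f3)
  back <- read.csv(f3, check.names = FALSE)
  expect_equal(back$`1899`, c(1, 0))
})
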