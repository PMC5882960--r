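make_labeled_series <- function(years = 1979:2016) {
  grid <- expand.grid(month = 1:12, year = years)
  monthly_series(grid$year, grid$month, 100 * grid$year + grid$month,
                 variable = "LAB")
}

test_that("harmonic deseasonalization removes pure annual and semi-annual cycles", {
  grid <- expand.grid(month = 1:12, year = 2000:2009)
  for (period in c(12, 6)) {
    v <- 5 + 3 * sin(2 * pi * grid$month / period + 0.7)
    ms <- monthly_series(grid$year, grid$month, v)
    res <- deseasonalize(ms)
    expect_lt(max(abs(res$value)), 1e-6)
  }
  expect_error(deseasonalize(monthly_series(rep(2000, 12), 1:12, rnorm(12))),
               "3 years")
})

test_that("deseasonalization of white noise only absorbs its harmonic df", {
  set.seed(16)
  grid <- expand.grid(month = 1:12, year = 1901:2000)
  ratios <- replicate(100, {
    v <- rnorm(1200)
    var(deseasonalize(monthly_series(grid$year, grid$month, v))$value) / var(v)
  })
  expect_lt(abs(mean(ratios) - 1), 0.02)
})

test_that("the dynamic-topography index is the monthly box difference", {
  grid <- expand.grid(month = 1:12, year = 2000:2004)
  north <- monthly_series(grid$year, grid$month, rep(0.10, nrow(grid)))
  central <- monthly_series(grid$year, grid$month, rep(0.04, nrow(grid)))
  idx <- adt_index(north, central)
  expect_equal(idx$value, rep(0.06, nrow(grid)))
  expect_equal(adt_index(north, north)$value, rep(0, nrow(grid)))
  expect_equal(adt_index(central, north)$value, -idx$value)
  short <- monthly_series(2000, 1, 0.5)
  expect_error(adt_index(north, short), "align")
})

test_that("deseasonalizing commutes with differencing the boxes", {
  set.seed(17)
  grid <- expand.grid(month = 1:12, year = 1990:2009)
  north <- monthly_series(grid$year, grid$month,
                          2 * sin(2 * pi * grid$month / 12) + rnorm(240))
  central <- monthly_series(grid$year, grid$month,
                            sin(2 * pi * grid$month / 6) + rnorm(240))
  a <- adt_index(deseasonalize(north), deseasonalize(central))
  b <- deseasonalize(adt_index(north, central))
  expect_lt(max(abs(a$value - b$value)), 1e-10)
})

test_that("growth-year alignment gathers the documented calendar cells", {
  fr <- align_to_growth_year(make_labeled_series())
  row2015 <- fr[fr$growth_year == 2015, ]
  expect_equal(row2015$Oct, 201410)   # October of the previous calendar year
  expect_equal(row2015$pApr, 201404)  # April preceding increment deposition
  expect_equal(row2015$Sep, 201509)
  expect_equal(row2015$Jan, 201501)
  expect_equal(names(fr)[-1],
               c("pApr", "pMay", "pJun", "pJul", "pAug", "pSep",
                 "Oct", "Nov", "Dec", "Jan", "Feb", "Mar",
                 "Apr", "May", "Jun", "Jul", "Aug", "Sep"))
})

test_that("incomplete growth years are dropped", {
  grid <- expand.grid(month = 1:12, year = 1980:1985)
  ms <- monthly_series(grid$year, grid$month, rnorm(nrow(grid)))
  expect_warning(fr <- align_to_growth_year(ms, growth_years = 1980:1985),
                 "incomplete")
  # a series starting 1980-01 first completes growth year 1981
  expect_equal(min(fr$growth_year), 1981)
})

test_that("spearman correlation matches mid-rank arithmetic and cor.test", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$r, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$r, -1)
  sp <- spearman_cor(c(1, 2, 2, 4), c(1, 3, 2, 4))
  expect_equal(sp$r, 4.5 / sqrt(22.5), tolerance = 1e-12)
  # independent oracle: cor.test on a tie-free small sample (exact p)
  set.seed(18)
  x <- rnorm(8); y <- rnorm(8)
  ours <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  # large-sample t approximation against cor.test's
  x <- rnorm(40); y <- x + rnorm(40)
  ours <- spearman_cor(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)
  expect_warning(out <- spearman_cor(rep(1, 12), rnorm(12)), "variance")
  expect_true(is.na(out$r))
})

test_that("spearman correlation is invariant under monotone transforms", {
  set.seed(19)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$r, base$r)
  expect_equal(spearman_cor(x, y^3)$r, base$r)
  expect_equal(spearman_cor(qlogis(pnorm(x)), exp(y))$p, base$p)
})

test_that("the monthly correlation table flags the self-correlated cell", {
  set.seed(20)
  grid <- expand.grid(month = 1:12, year = 1978:2016)
  ms <- monthly_series(grid$year, grid$month, rnorm(nrow(grid)),
                       variable = "V")
  fr <- align_to_growth_year(ms)
  chron_df <- data.frame(year = fr$growth_year, index = fr$Feb)
  tab <- monthly_correlation_table(chron_df, list(V = fr))
  feb <- tab[tab$month == "Feb", ]
  expect_equal(feb$r, 1)
  expect_identical(feb$tier, "95%")
  # tier assignment is consistent with p everywhere
  expect_true(all((tab$tier == "95%") == (tab$p < 0.05)))
  expect_true(all((tab$tier == "90%") == (tab$p >= 0.05 & tab$p < 0.10)))
  expect_equal(attr(tab, "expected_false_positives_95"), 0.05 * 18)
})

test_that("short overlaps are computed but flagged", {
  grid <- expand.grid(month = 1:12, year = 2000:2011)
  ms <- monthly_series(grid$year, grid$month, rnorm(nrow(grid)))
  fr <- align_to_growth_year(ms)
  chron_df <- data.frame(year = fr$growth_year,
                         index = rnorm(nrow(fr)) + 1)
  expect_warning(tab <- monthly_correlation_table(chron_df, list(X = fr)),
                 "overlap")
  expect_true(all(tab$low_overlap))
  expect_equal(nrow(tab), 18)
})

test_that("seasonal means honour presets and reject unknown columns", {
  fr <- align_to_growth_year(make_labeled_series())
  all18 <- seasonal_mean(fr, names(fr)[-1])
  expect_equal(all18$value, unname(rowMeans(as.data.frame(fr)[, -1])))
  one <- seasonal_mean(fr, "Feb")
  expect_equal(one$value, fr$Feb)
  jja <- seasonal_mean(fr, "JJA")
  expect_equal(jja$value, rowMeans(cbind(fr$Jun, fr$Jul, fr$Aug)))
  octsep <- seasonal_mean(fr, "OctSep")
  expect_equal(octsep$value,
               unname(rowMeans(as.data.frame(fr)[, c("Oct", "Nov", "Dec",
                                                     "Jan", "Feb", "Mar",
                                                     "Apr", "May", "Jun",
                                                     "Jul", "Aug", "Sep")])))
  expect_error(seasonal_mean(fr, "Smarch"), "unknown month")
  expect_error(seasonal_mean(fr, character(0)), "nonempty")
})

test_that("stepwise selection keeps a self-candidate and skips collinear ones", {
  set.seed(22)
  y <- rnorm(30)
  X <- data.frame(self = y, n1 = rnorm(30), n2 = rnorm(30))
  sw <- suppressWarnings(stepwise_forward(y, X))  # exact fit upsets summary.lm
  expect_identical(sw$selected[1], "self")
  expect_equal(sw$multiple_r, 1, tolerance = 1e-10)
  # a duplicated candidate is collinear once its twin entered
  X2 <- data.frame(a = y + rnorm(30, 0, 0.1), b = NA, c = rnorm(30))
  X2$b <- X2$a
  expect_warning(sw2 <- stepwise_forward(y, X2), "collinear")
  expect_false("b" %in% sw2$selected)
  expect_error(stepwise_forward(y, X["self"]), "2 candidate")
  expect_error(stepwise_forward(y[1:5], X[1:5, ]), "10 complete")
})

test_that("prewhitening removes first-order autocorrelation", {
  set.seed(23)
  for (phi in c(0.5, 0.7)) {
    x <- as.numeric(stats::filter(rnorm(5000), phi, method = "recursive"))
    res <- prewhiten_ar1(x)
    expect_length(res, 4999)
    expect_lt(abs(first_order_autocorrelation(as.numeric(res))), 0.05)
    expect_equal(attr(res, "phi"), phi, tolerance = 0.05)
    expect_equal(mean(res), mean(x), tolerance = 1e-10)
  }
  w <- rnorm(2000)
  expect_lt(abs(attr(prewhiten_ar1(w), "phi")), 0.05)
  expect_error(prewhiten_ar1(rep(1, 50)), "variance")
})

test_that("the analysis report orchestrates all stages reproducibly", {
  run_once <- function() {
    grid <- expand.grid(month = 1:12, year = 1975:2016)
    set.seed(24)
    sst <- monthly_series(grid$year, grid$month,
                          15 + 4 * sin(2 * pi * grid$month / 12) +
                            rnorm(nrow(grid)), variable = "SST")
    adt <- monthly_series(grid$year, grid$month, rnorm(nrow(grid), 0, 0.05),
                          variable = "ADT")
    chron_df <- data.frame(year = 1980:2016,
                           index = 1 + 0.1 * rnorm(37))
    analysis_report(chron_df, list(SST = sst, ADT = adt))
  }
  rep1 <- run_once()
  rep2 <- run_once()
  expect_s3_class(rep1, "analysis_report")
  expect_equal(nrow(rep1$correlations), 36)
  expect_named(rep1$seasonal, c("SST_OctSep", "ADT_OctSep"))
  expect_false(is.null(rep1$stepwise_prewhitened))
  expect_identical(rep1$correlations$r, rep2$correlations$r)
  expect_identical(rep1$stepwise$multiple_r, rep2$stepwise$multiple_r)
  dir <- withr::local_tempdir()
  files <- write_analysis_report(rep1, dir)
  expect_true(all(file.exists(files)))
  sw <- jsonlite::read_json(files[["stepwise"]])
  expect_true(!is.null(sw$stepwise))
})
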