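test_that("a chronology of identical series equals any member", {
  coll <- as_detrended(make_common_signal_collection(10, 40, rbar = 1))
  for (avg in c("biweight", "mean")) {
    chron <- build_chronology(coll, averaging = avg)
    expect_equal(chron$index, coll[[1]]$indices, tolerance = 1e-10)
    expect_equal(chron$sample_depth, rep(10L, 40))
    expect_equal(chron$rbar, 1, tolerance = 1e-12)
  }
})

test_that("biweight averaging resists a single outlier year", {
  coll <- as_detrended(make_common_signal_collection(20, 40, rbar = 1,
                                                     seed = 4))
  clean_mean <- build_chronology(coll, "mean")$index
  dirty <- coll
  dirty[[1]]$indices[20] <- dirty[[1]]$indices[20] + 5
  dev_bi <- abs(build_chronology(dirty, "biweight")$index[20] -
                  clean_mean[20])
  dev_mean <- abs(build_chronology(dirty, "mean")$index[20] - clean_mean[20])
  expect_lt(dev_bi, 0.2 * dev_mean)
})

test_that("sample depth tracks coverage on a staggered collection", {
  coll <- as_detrended(make_common_signal_collection(6, 30, rbar = 1,
                                                     stagger = 2))
  chron <- build_chronology(coll)
  m <- as_year_matrix(coll)
  expect_equal(chron$sample_depth, unname(rowSums(!is.na(m))))
})

test_that("chronologies are invariant to series order", {
  coll <- as_detrended(make_common_signal_collection(8, 35, rbar = 0.5,
                                                     stagger = 3, seed = 14))
  c1 <- build_chronology(coll)
  c2 <- build_chronology(coll[sample(8)])
  expect_equal(c1$index, c2$index)
  expect_equal(c1$sample_depth, c2$sample_depth)
})

test_that("residual-mode indices are recentred to a dimensionless index", {
  coll <- series_collection(lapply(1:3, function(i)
    detrended_series(sprintf("R%d", i), 1950, rnorm(30, mean = -2),
                     mode = "residual")))
  chron <- build_chronology(coll, "mean")
  expect_equal(mean(chron$index), 1, tolerance = 1e-10)
})

test_that("EPS closed form evaluates, collapses and increases as expected", {
  expect_equal(eps_from_rbar(10, 1), 1)
  expect_equal(eps_from_rbar(1, 0.3), 0.3)
  expect_equal(eps_from_rbar(10, 0.615), 0.941, tolerance = 1e-3)
  # strictly increasing in n and in rbar
  eps_n <- eps_from_rbar(1:50, 0.4)
  expect_true(all(diff(eps_n) > 0))
  eps_r <- eps_from_rbar(10, seq(0.05, 1, 0.05))
  expect_true(all(diff(eps_r) > 0))
  expect_warning(out <- eps_from_rbar(10, -0.2), "undefined")
  expect_true(is.na(out))
  expect_error(eps_from_rbar(0, 0.5), ">= 1")
})

test_that("running EPS window bookkeeping matches the 30/29 convention", {
  coll <- as_detrended(make_common_signal_collection(12, 63, rbar = 1,
                                                     first_year = 1954))
  re <- running_eps(coll, window = 30, overlap = 29)
  expect_equal(nrow(re), 34)   # 63-yr span, stride 1
  expect_equal(re$start_year, 1954:1987)
  expect_equal(re$end_year, re$start_year + 29)
  # noise-free common signal: EPS = 1 in every defined window
  expect_equal(re$eps, rep(1, 34), tolerance = 1e-10)
  expect_equal(re$n_effective, rep(12, 34))
})

test_that("running EPS rises with replication", {
  eps_by_n <- vapply(c(15, 30), function(n) {
    med <- vapply(1:10, function(s) {
      res <- suppressWarnings(
        simulate_and_recover(default_scenario(seed = s, n_shells = n)))
      median(res$chron$running_eps$eps, na.rm = TRUE)
    }, numeric(1))
    median(med)
  }, numeric(1))
  expect_gt(eps_by_n[2], eps_by_n[1])
})

test_that("windows with too few qualifying series are undefined", {
  coll <- as_detrended(make_common_signal_collection(2, 15, rbar = 1,
                                                     first_year = 1950))
  solo <- series_collection(c(unclass(coll),
                              list(detrended_series("LONE", 1920,
                                                    runif(80, 0.8, 1.2)))))
  re <- running_eps(solo, window = 12, overlap = 11)
  early <- re[re$end_year < 1950, ]
  expect_true(all(is.na(early$eps)))
})

test_that("truncation respects the joint depth and EPS rule", {
  years <- 1954:2016
  depth <- ifelse(years >= 1973, 12L, 5L)
  re <- data.frame(start_year = 1954:1987,
                   center_year = 1954:1987 + 14.5,
                   end_year = 1954:1987 + 29,
                   rbar = 0.5, n_effective = 10,
                   eps = ifelse(1954:1987 >= 1979, 0.90, 0.80))
  chron <- chronology(years, rep(1, 63), depth, running_eps = re)
  trunc <- truncate_chronology(chron, min_depth = 10, eps_threshold = 0.85)
  expect_equal(trunc$truncation_year, 1979L)
  expect_true(all(trunc$provisional == (years < 1979)))

  # all-depth-adequate fixture truncates at the first year
  trunc2 <- truncate_chronology(
    chronology(years, rep(1, 63), rep(12L, 63),
               running_eps = transform(re, eps = 0.95)),
    min_depth = 10, eps_threshold = 0.85)
  expect_equal(trunc2$truncation_year, 1954L)

  # degenerate thresholds keep everything
  trunc3 <- truncate_chronology(chron, min_depth = 1, eps_threshold = 0)
  expect_equal(trunc3$truncation_year, 1954L)

  # unsatisfiable rule yields an empty retained span with a warning
  expect_warning(
    trunc4 <- truncate_chronology(
      chronology(years, rep(1, 63), depth, running_eps = re),
      min_depth = 50, eps_threshold = 0.85),
    "never satisfied")
  expect_equal(nrow(chronology_series(trunc4)), 0)
})

test_that("closed-form EPS matches a brute-force variance-ratio estimate", {
  set.seed(15)
  for (rbar in c(0.3, 0.6)) {
    n <- 10
    T <- 4000
    pop <- rnorm(T)
    xs <- sapply(1:n, function(i) sqrt(rbar) * pop + sqrt(1 - rbar) * rnorm(T))
    eps_mc <- cor(rowMeans(xs), pop)^2
    expect_equal(eps_mc, eps_from_rbar(n, rbar), tolerance = 0.03)
  }
})
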