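# Kruskal-Wallis, Pearson validation, quantile-regression outlier filter
# and the screening tables.

test_that("Kruskal-Wallis H matches hand computation and base R", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$statistic, 27 / 7)   # R1 = 6, R2 = 15
  expect_equal(kw$df, 1)
  # identical groups (all ties across groups): H = 0 by the convention
  kw0 <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw0$statistic, 0, tolerance = 1e-12)
  con <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(con$statistic, 0)
  expect_equal(con$p.value, 1)
  # rank invariance under strictly monotone transforms
  set.seed(61)
  g <- list(rnorm(8), rnorm(6, 1), rnorm(7, 2))
  expect_equal(kruskal_wallis(g)$p.value,
               kruskal_wallis(lapply(g, function(x) exp(3 * x)))$p.value)
  # cross-check against stats::kruskal.test on random data with ties
  for (i in 1:25) {
    g <- lapply(sample(2:5, sample(2:4, 1), TRUE),
                function(n) sample(1:6, n + 2, TRUE))
    kw <- kruskal_wallis(g)
    ref <- stats::kruskal.test(unlist(g), rep(seq_along(g), lengths(g)))
    if (is.nan(ref$statistic)) next
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(kw$p.value, ref$p.value, tolerance = 1e-9)
  }
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("Kruskal-Wallis chi-square p agrees with Monte-Carlo permutation", {
  # group sizes of a few dozen: large enough that the chi-square upper
  # tail is within Monte-Carlo resolution of the permutation law
  set.seed(62)
  for (i in 1:10) {
    g <- lapply(rep(sample(30:50, 1), sample(2:3, 1)),
                function(n) rnorm(n, sample(0:1, 1) * 0.4))
    kw <- kruskal_wallis(g)
    B <- 4000
    pperm <- oracle_kw_perm_p(g, B)
    se <- sqrt(pperm * (1 - pperm) / B)
    expect_lt(abs(kw$p.value - pperm), 3 * se)
  }
})

test_that("Pearson correlation handles exact, missing and degenerate cases", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  expect_equal(pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  # pairwise deletion of missing values
  expect_equal(pearson_correlation(c(1, 2, 3, 4, NA), c(2, 1, 4, 3, 10)), 0.6)
  expect_true(is.na(pearson_correlation(c(1, 1, 1), c(1, 2, 3))))
  expect_true(is.na(pearson_correlation(c(1, 2), c(3, 4))))
  # symmetry and affine invariance
  set.seed(63)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(pearson_correlation(a, b), pearson_correlation(b, a))
  expect_equal(pearson_correlation(3 * a + 2, b), pearson_correlation(a, b))
})

test_that("quantile regression minimizes pinball loss and satisfies the quantile property", {
  set.seed(64)
  x <- runif(80, 0, 10)
  y <- 2 + 0.5 * x + runif(80, -1, 1)
  for (tau in c(0.1, 0.25, 0.5, 0.9)) {
    fit <- quantile_regression_fit(x, y, tau)
    # grid-search oracle over slope/intercept
    best <- Inf
    for (b in seq(0.2, 0.8, by = 0.01)) for (a in seq(0.5, 4, by = 0.02)) {
      r <- y - a - b * x
      l <- sum(r * (tau - (r < 0)))
      if (l < best) best <- l
    }
    expect_lte(fit$loss, best + 1e-9)
    below <- mean(y < fit$intercept + fit$slope * x - 1e-12)
    expect_lt(abs(below - tau), 2 / sqrt(80))
  }
  # constant covariate falls back to the empirical quantile
  fit <- quantile_regression_fit(rep(1, 20), 1:20, 0.25)
  expect_equal(fit$slope, 0)
  expect_equal(fit$intercept, unname(quantile(1:20, 0.25, type = 1)))
})

test_that("the outlier filter removes gross outliers and passes clean lines", {
  mk <- function(y, day) data.frame(
    plant_id = sprintf("P%03d", seq_along(y)), variety = "V01",
    treatment = "unstressed", stage = "V2", day = day, view = "vertical",
    trait_name = "area", value = y, stringsAsFactors = FALSE)
  # data exactly on a line: nothing removed
  day <- rep(c(0, 7, 14), length.out = 30)
  lin <- mk(5 + 2 * day, day)
  res <- quantile_outlier_filter(lin, taus = c(0.05, 0.95))
  expect_equal(nrow(res$table), 30)
  expect_false(any(res$report$flags$removed))
  # one gross outlier on y = x + noise is removed, few others
  set.seed(65)
  day <- rep(0:9, each = 10)
  y <- day + runif(100, -1, 1)
  y[100] <- day[100] + 50
  tab <- mk(y, day)
  res <- quantile_outlier_filter(tab, taus = c(0.05, 0.95))
  expect_true(res$report$flags$removed[100])
  expect_lte(sum(res$report$flags$removed), ceiling(100 * 0.1) + 1)
  # quantile property: about 25% of points below the tau = 0.25 line
  fit <- quantile_regression_fit(day, y, 0.25)
  below <- mean(y < fit$intercept + fit$slope * day)
  expect_lt(abs(below - 0.25), 2 / sqrt(100))
  # removed rows lie strictly outside the fitted band
  lines <- res$report$lines
  lo <- lines[lines$tau == 0.05, ]; hi <- lines[lines$tau == 0.95, ]
  bad <- which(res$report$flags$removed)
  expect_true(all(y[bad] < lo$intercept + lo$slope * day[bad] |
                    y[bad] > hi$intercept + hi$slope * day[bad]))
  # small cells pass through with a warning
  small <- mk((1:5) + c(0, 0, 0, 0, 100), rep(1, 5))
  expect_warning(res2 <- quantile_outlier_filter(small), "unfiltered")
  expect_equal(nrow(res2$table), 5)
})

test_that("the outlier filter is approximately idempotent on clean data", {
  set.seed(66)
  mk <- function(n) data.frame(
    plant_id = sprintf("P%03d", 1:n), variety = "V01", treatment = "drought",
    stage = "V2", day = rep(0:4, length.out = n), view = "vertical",
    trait_name = "area", value = rnorm(n), stringsAsFactors = FALSE)
  tab <- mk(200)
  once <- quantile_outlier_filter(tab)
  twice <- quantile_outlier_filter(once$table)
  expect_lte(sum(twice$report$flags$removed), ceiling(0.1 * nrow(once$table)))
  expect_gte(nrow(twice$table), 0.85 * nrow(once$table))
})

test_that("screening tables carry df = k - 1 and respect the alpha flag", {
  tr <- quick_trial(seed = 67, days = c(0L, 14L), n_varieties = 3)
  long <- state_trait_long(
    trial_config(n_varieties = 3, plots_unstressed = 1, plots_treated = 1,
                 exclude_from_second_plot = 0, days = c(0L, 14L),
                 views = "vertical", seed = 67),
    stress_model())
  st <- build_screening_tables(long, grouping = c("treatment", "variety"),
                               alpha = 0.05)
  expect_true(all(st$df[st$grouping == "treatment"] == 1, na.rm = TRUE))
  expect_true(all(st$df[st$grouping == "variety"] ==
                    st$n_groups[st$grouping == "variety"] - 1, na.rm = TRUE))
  ok <- !is.na(st$p_value)
  expect_true(all((st$p_value[ok] < 0.05) == st$significant[ok]))
  expect_true(all(st$p_value[ok] >= 0 & st$p_value[ok] <= 1))
  # single-group cells emit a missing p, not an error
  solo <- long[long$treatment == "drought", ]
  st1 <- build_screening_tables(solo, grouping = "treatment")
  expect_true(all(is.na(st1$p_value)))
})
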