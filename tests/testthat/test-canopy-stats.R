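test_that("difference statistics follow the threshold definitions", {
  ds <- difference_stats(rep(0, 3), c(0.4, -0.6, 1.0), thresholds = 0.3)
  expect_equal(ds$p_k, 1)
  expect_equal(ds$mean_k, mean(c(0.4, 0.6, 1.0)))
  # empty-exceedance rule: proportion and mean are zero
  ds0 <- difference_stats(0, 0.1, thresholds = 0.3)
  expect_equal(ds0$p_k, 0)
  expect_equal(ds0$mean_k, 0)
  expect_error(difference_stats(numeric(0), numeric(0)), "no points")
  expect_error(difference_stats(1:3, 1:2), "equal length")
})

test_that("p_k is non-increasing and mean_k >= k for arbitrary inputs", {
  set.seed(21)
  for (r in 1:20) {
    d <- rnorm(300, 0, runif(1, 0.1, 1.5))
    ds <- difference_stats(rep(0, 300), d)
    expect_true(all(diff(ds$p_k) <= 0))
    expect_true(all(ds$mean_k[ds$p_k > 0] >= ds$k[ds$p_k > 0]))
    expect_true(all(ds$p_k >= 0 & ds$p_k <= 1))
  }
})

test_that("height percentiles use the linear quantile rule above a cutoff", {
  hp <- height_percentiles(2:11, above = 1.8)
  expect_equal(unname(hp["h50"]), 6.5)
  expect_equal(unname(hp["hmean"]), mean(2:11))
  hc <- height_percentiles(rep(5, 20))
  expect_true(all(hc[1:9] == 5))
  h1 <- height_percentiles(c(0.3, 1.2, 9.4))
  expect_true(all(h1[1:9] == 9.4))
  expect_error(height_percentiles(c(0.2, 1.0)), "above")
})

test_that("Lorey's height is the basal-area weighted mean", {
  expect_equal(lorey_height(30, 12), 12)
  expect_equal(lorey_height(c(15, 15), c(10, 20)), 15)
  expect_equal(lorey_height(c(10, 20), c(10, 20)), 18)
  set.seed(3)
  dbh <- runif(50, 5, 40); h <- runif(50, 4, 25)
  lh <- lorey_height(dbh, h)
  expect_true(lh >= min(h) && lh <= max(h))
  expect_error(lorey_height(c(10, -1), c(5, 5)), "positive")
})

# draw plausible plot percentile metrics from per-plot height samples
make_plots <- function(n = 41, seed = 17, beta = c(2, 1), noise = 0.1) {
  set.seed(seed)
  plots <- do.call(rbind, lapply(seq_len(n), function(i) {
    mu <- runif(1, 6, 20)
    h <- mu * rbeta(200, runif(1, 2, 5), 2)
    as.data.frame(t(height_percentiles(h, above = 1.8)))
  }))
  plots$Lh <- beta[1] + beta[2] * plots$h90 + rnorm(n, 0, noise)
  plots
}

test_that("stepwise selection recovers a generative percentile model", {
  plots <- make_plots()
  m <- fit_lorey_model(plots, k_folds = 10, seed = 1)
  expect_equal(m$terms[1], "h90")
  expect_equal(unname(coef(m)["h90"]), 1, tolerance = 0.1)
  expect_equal(unname(coef(m)["(Intercept)"]), 2, tolerance = 0.1)
  expect_gt(m$r_squared, 0.95)
  # deterministic under a fixed fold seed
  m2 <- fit_lorey_model(plots, k_folds = 10, seed = 1)
  expect_identical(coef(m), coef(m2))
  expect_identical(m$terms, m2$terms)
})

test_that("pure-noise responses keep the model small and weak", {
  plots <- make_plots(noise = 0)
  set.seed(99)
  plots$Lh <- rnorm(41)
  m <- fit_lorey_model(plots, k_folds = 10, seed = 1)
  expect_lte(length(m$terms), 2L)
  expect_lte(m$kfold_r_squared, 0.2)
})

test_that("a predictor equal to the response yields a perfect fit", {
  plots <- make_plots(noise = 0)
  plots$Lh <- plots$h90
  m <- suppressWarnings(fit_lorey_model(plots, k_folds = 10, seed = 1))
  expect_equal(m$r_squared, 1)
  expect_lt(m$rmse, 1e-8)
  expect_gte(m$r_squared, m$kfold_r_squared - 0.05)
})

test_that("degenerate designs and inputs error clearly", {
  plots <- make_plots()
  expect_error(fit_lorey_model(plots[1:5, ]), "at least")
  plots$h20 <- plots$h10          # exact collinearity
  expect_error(fit_lorey_model(plots), "collinear")
})

test_that("plot tables aggregate to per-plot Lorey's heights", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_id,slope_deg,dbh_cm,height_m",
               "1,12,10,10", "1,12,20,20", "2,30,30,12"), f)
  stems <- read_plot_table(f)
  lh <- lorey_by_plot(stems)
  expect_equal(lh$Lh, c(18, 12))
  expect_equal(lh$slope_deg, c(12, 30))
  writeLines(c("plot_id,slope_deg,dbh_cm,height_m", "1,12,-1,10"), f)
  expect_error(read_plot_table(f), "positive")
  writeLines("plot_id,dbh_cm", f)
  expect_error(read_plot_table(f), "missing column")
})

test_that("slope-proportion regression handles exact and degenerate cases", {
  s <- seq(0, 40, by = 5)
  f <- suppressWarnings(slope_proportion_regression(s, 0.01 * s + 0.02))
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 0.01)
  fc <- slope_proportion_regression(s, rep(0.2, length(s)))
  expect_equal(fc$r_squared, 0)
  expect_error(slope_proportion_regression(rep(10, 5), runif(5)), "variance")
  expect_error(slope_proportion_regression(1:2, 1:2), "at least 3")
})
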