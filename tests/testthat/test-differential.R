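demo_tables <- function() {
  peps <- data.frame(start = c(1, 4), end = c(5, 9),
                     sequence = c("GFLKA", "KAMHQR"),
                     stringsAsFactors = FALSE)
  manual_tables("demo", peps, c(30, 300),
    free_reps = list(list(c(1.0, 1.2, 1.1), c(1.5, 1.6, 1.4)),
                     list(c(0.5, 0.6, 0.4), c(0.9, 1.0, 0.8))),
    bound_reps = list(list(c(0.5, 0.6, 0.55), c(1.0, 1.1, 0.9)),
                      list(c(0.5, 0.6, 0.4), c(0.9, 1.0, 0.8))))
}

test_that("cell summaries report replicate mean, n-1 sd, and n", {
  tabs <- demo_tables()
  cells <- summarize_cells(tabs$free)
  c11 <- cells[cells$start == 1 & cells$timepoint_s == 30, ]
  expect_equal(c11$mean, 1.1)
  expect_equal(c11$sd, 0.1)
  expect_equal(c11$n, 3L)

  same <- tabs$free
  same$uptake_da <- 1.5
  expect_equal(unique(summarize_cells(same)$sd), 0)

  single <- tabs$free[tabs$free$replicate == 1, ]
  expect_warning(out <- summarize_cells(single), "single replicate")
  expect_equal(nrow(out), 0L)
})

test_that("differential uptake uses bound minus free with per-peptide sums", {
  tabs <- demo_tables()
  d <- delta_uptake(summarize_cells(tabs$free), summarize_cells(tabs$bound))
  d11 <- d[d$start == 1 & d$timepoint_s == 30, ]
  expect_equal(d11$delta, 0.55 - 1.1)      # protection direction
  expect_equal(d11$sum_delta, (0.55 - 1.1) + (1.0 - 1.5))
  # identical states give all-zero deltas
  d0 <- delta_uptake(summarize_cells(tabs$free), summarize_cells(tabs$free))
  expect_true(all(d0$delta == 0))
  # unmatched cells are dropped with a warning
  part <- tabs$bound[tabs$bound$start == 1, ]
  expect_warning(dm <- delta_uptake(summarize_cells(tabs$free),
                                    summarize_cells(part)), "unmatched")
  expect_equal(sort(unique(dm$start)), 1)
})

test_that("pooled standard deviation is df-weighted across all cells", {
  cells <- data.frame(start = 1, end = 5, sequence = "GFLKA",
                      state = c("free", "bound"), timepoint_s = 30,
                      mean = 1, sd = c(0.1, 0.3), n = 3L,
                      stringsAsFactors = FALSE)
  pool <- pooled_sd(cells[1, ], cells[2, ])
  expect_equal(pool$s_pooled, sqrt((0.01 + 0.09) / 2))
  expect_equal(pool$df_pooled, 4L)

  same <- cells; same$sd <- 0.2
  expect_equal(pooled_sd(same[1, ], same[2, ])$s_pooled, 0.2)
  zero <- cells; zero$sd <- 0
  expect_equal(pooled_sd(zero[1, ], zero[2, ])$s_pooled, 0)
})

test_that("global threshold matches the t-quantile closed form", {
  expect_equal(global_threshold(0, 4), 0)
  expect_equal(global_threshold(0.1, 4, 3, 3, 0.05),
               2.776445105198 * 0.1 * sqrt(2 / 3), tolerance = 1e-9)
  # normal limit at large df
  expect_equal(global_threshold(1, 1e7, 3, 3, 0.05),
               qnorm(0.975) * sqrt(2 / 3), tolerance = 1e-4)
  # homogeneous of degree 1 in s_pooled
  expect_equal(global_threshold(0.26, 40), 2 * global_threshold(0.13, 40))
  expect_error(global_threshold(0.1, 0), "df_pooled")
})

test_that("Welch test agrees with reference implementations and is symmetric", {
  # frozen external reference values
  w <- welch_ttest(c(1.0, 1.1, 0.9), c(0.5, 0.6, 0.4))
  expect_equal(w$t, -6.12372435695795, tolerance = 1e-10)
  expect_equal(w$p, 0.003602232609104, tolerance = 1e-10)

  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1), mean = runif(1))
    w <- welch_ttest(x, y)
    b <- brute_welch(x, y)
    expect_equal(w$p, b$p, tolerance = 1e-12)
    expect_equal(w$t, b$t, tolerance = 1e-12)
    sw <- welch_ttest(y, x)
    expect_equal(sw$t, -w$t)
    expect_equal(sw$p, w$p)
  }

  same <- c(1, 2, 3)
  expect_equal(welch_ttest(same, same)$p, 1)
  expect_equal(welch_ttest(c(1, 1), c(1, 1)), list(t = 0, df = 2L, p = 1))
  expect_error(welch_ttest(1, c(1, 2)), "2 replicates")
})

test_that("vectorized Welch statistics match the two-vector route", {
  set.seed(32)
  for (i in 1:50) {
    x <- rnorm(3, sd = runif(1, 0.05, 1)); y <- rnorm(3, mean = runif(1))
    w <- welch_ttest(x, y)
    v <- hdxbind:::.welch_from_summaries(mean(x), sd(x), 3L,
                                         mean(y), sd(y), 3L)
    expect_equal(v$t, w$t, tolerance = 1e-10)
    expect_equal(v$df, w$df, tolerance = 1e-10)
    expect_equal(v$p, w$p, tolerance = 1e-10)
  }
})

test_that("hybrid criterion requires both magnitude and p-value", {
  d <- data.frame(delta = c(-0.50, -0.20, 0.40),
                  welch_p = c(0.01, 0.001, 0.30))
  out <- hybrid_significance(d, threshold = 0.3184, alpha_ttest = 0.05)
  expect_equal(out$significant, c(TRUE, FALSE, FALSE))
  expect_equal(out$direction, c("protected", "none", "none"))
  dep <- hybrid_significance(data.frame(delta = 0.4, welch_p = 0.01),
                             threshold = 0.3184)
  expect_equal(dep$direction, "deprotected")
})

test_that("the full hybrid fit honors threshold overrides and peptide relabeling", {
  truth <- simulate_system(length = 80, seed = 14)
  map <- simulate_digestion(truth$protein, seed = 14)
  tabs <- simulate_uptake_tables(truth, map, experiment_design(seed = 14))
  fit <- hdx_hybrid(tabs$free, tabs$bound)
  expect_s3_class(fit, "hdx_hybrid")
  expect_equal(fit$params$threshold, fit$params$threshold_pooled)

  over <- hdx_hybrid(tabs$free, tabs$bound, threshold = 0.3184)
  expect_equal(over$params$threshold, 0.3184)
  expect_equal(over$params$threshold_pooled, fit$params$threshold_pooled)

  # shuffling input row order leaves flags per peptide unchanged
  shuf <- function(df) df[sample(nrow(df)), ]
  set.seed(1)
  fit2 <- hdx_hybrid(shuf(tabs$free), shuf(tabs$bound))
  key <- function(f) paste(f$deltas$start, f$deltas$end, f$deltas$timepoint_s)
  expect_equal(fit2$deltas$significant[order(key(fit2))],
               fit$deltas$significant[order(key(fit))])

  # residual CSV export is stable and complete
  f <- tempfile(fileext = ".csv")
  write_residual_csv(fit, f)
  df <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(names(df), c("peptide_index", "start", "end", "timepoint_s",
                            "delta_da", "sum_delta_da", "welch_p",
                            "significant", "direction"))
  expect_equal(nrow(df), nrow(fit$deltas))
})
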