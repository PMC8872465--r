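test_that("rank_regions orders by r with deterministic tie-breaks", {
  m <- matrix(NA_real_, 19, 19)
  m[1, 2] <- 0.4
  expect_equal(rank_regions(m, "negative")[1, c("x", "y")],
               data.frame(x = 1L, y = 2L))
  expect_equal(rank_regions(m, "positive")[1, c("x", "y")],
               data.frame(x = 1L, y = 2L))
  m[2, 5] <- -0.9; m[3, 8] <- -0.2; m[4, 9] <- 0.7
  expect_equal(unlist(rank_regions(m, "negative")[1, c("x", "y")]),
               c(x = 2, y = 5))
  expect_equal(unlist(rank_regions(m, "positive")[1, c("x", "y")]),
               c(x = 4, y = 9))
  # tie: shorter region first, then smaller start
  m2 <- matrix(NA_real_, 19, 19)
  m2[2, 10] <- -0.5; m2[6, 9] <- -0.5; m2[3, 6] <- -0.5
  rk <- rank_regions(m2, "negative")
  # equal r and equal length (3,6)/(6,9): smaller start first; longest last
  expect_equal(rk$x, c(3, 6, 2))
  expect_equal(rk$y, c(6, 9, 10))
  expect_error(rank_regions(matrix(NA_real_, 3, 3), "negative"), "undefined")
})

test_that("degenerate sampling (full panel, 1 rep) equals the full-panel top-k", {
  p <- tiny_panel(8, seed = 41)
  act <- activities_from(p, runif(8, 10, 100))
  cm <- correlation_map(p, act, "SM", 50)
  top <- rank_regions(cm, "negative")[1, ]
  cfg <- sampling_config(n_reps = 1, subset_size = 8, top_k = 1,
                         sign = "negative", seed = 1)
  summ <- sampling_frequencies(p, act, cfg)
  expect_equal(sum(summ$start_hist), 1L)
  expect_equal(which(summ$start_hist == 1L), top$x, ignore_attr = TRUE)
  expect_equal(which(summ$end_hist == 1L), top$y, ignore_attr = TRUE)
  expect_equal(unname(summ$modal_region), c(top$x, top$y))
})

test_that("histograms conserve counts and runs are seed-deterministic", {
  p <- tiny_panel(10, seed = 42)
  act <- activities_from(p, runif(10, 10, 100))
  cfg <- sampling_config(n_reps = 50, subset_size = 5, top_k = 10,
                         sign = "positive", seed = 9)
  s1 <- sampling_frequencies(p, act, cfg)
  expect_equal(sum(s1$start_hist), 500L)
  expect_equal(sum(s1$end_hist), 500L)
  expect_equal(sum(s1$region_hist$count), 500L)
  s2 <- sampling_frequencies(p, act, cfg)
  expect_identical(s1, s2)
  s3 <- sampling_frequencies(p, act,
                             sampling_config(n_reps = 50, subset_size = 5,
                                             top_k = 10, sign = "positive",
                                             seed = 10))
  expect_false(identical(s1$start_hist, s3$start_hist))
  expect_error(sampling_config(subset_size = 2), "too small")
})

test_that("split_correlations on an exact linear activity gives |r| = 1, t = 0", {
  p <- generate_panel(simulation_params(n_sirnas = 26, seed = 6))
  tm25 <- vapply(p$guide_core,
                 function(g) melting_temperature(substr(g, 2, 5)), 0,
                 USE.NAMES = FALSE)
  act <- activities_from(p, 150 + tm25)
  cfg <- sampling_config(n_reps = 20, subset_size = 13, seed = 2)
  sc <- split_correlations(p, act, c(2, 5), cfg)
  expect_equal(sc$train_r, rep(1, 20), tolerance = 1e-9)
  expect_equal(sc$valid_r, rep(1, 20), tolerance = 1e-9)
  expect_equal(sc$t_stat, 0, tolerance = 1e-6)
  expect_error(split_correlations(p, act, c(1, 1), cfg), "not defined")
  expect_error(split_correlations(p, act, c(2, 5),
                                  sampling_config(subset_size = 24, seed = 1)),
               "config error")
})

test_that("student_t_test matches the pooled-variance hand formula", {
  tt <- student_t_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt[["t"]], -1.2247, tolerance = 1e-3 / 1.2247)
  expect_equal(tt[["df"]], 4)
  # independent p oracle: numeric integration of the t density
  dens <- function(x, df) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
    (1 + x^2 / df)^(-(df + 1) / 2)
  p_oracle <- 2 * integrate(dens, -Inf, -abs(tt[["t"]]), df = 4)$value
  expect_equal(tt[["p"]], p_oracle, tolerance = 1e-6)
  # degenerate branches
  expect_equal(student_t_test(c(1, 1), c(1, 1))[c("t", "p")], c(t = 0, p = 1))
  z <- student_t_test(c(1, 1), c(2, 2))
  expect_true(is.infinite(z[["t"]]) && z[["p"]] == 0)
  # symmetry
  a <- rnorm(6); b <- rnorm(8)
  expect_equal(student_t_test(a, b)[["t"]], -student_t_test(b, a)[["t"]])
  expect_equal(student_t_test(a, b)[["p"]], student_t_test(b, a)[["p"]])
})

test_that("student_t_test agrees with stats::t.test on random input", {
  set.seed(19)
  for (i in 1:25) {
    a <- rnorm(sample(3:12, 1)); b <- rnorm(sample(3:12, 1), mean = 0.5)
    tt <- student_t_test(a, b)
    ref <- stats::t.test(a, b, var.equal = TRUE)
    expect_equal(tt[["t"]], unname(ref$statistic), tolerance = 1e-9)
    expect_equal(tt[["p"]], ref$p.value, tolerance = 1e-9)
    tw <- student_t_test(a, b, welch = TRUE)
    refw <- stats::t.test(a, b)
    expect_equal(tw[["t"]], unname(refw$statistic), tolerance = 1e-9)
    expect_equal(tw[["p"]], refw$p.value, tolerance = 1e-9)
  }
})

test_that("combined_region_correlation implements the three schemes", {
  p <- generate_panel(simulation_params(n_sirnas = 26, seed = 13))
  tmA <- vapply(p$guide_core,
                function(g) melting_temperature(substr(g, 2, 5)), 0,
                USE.NAMES = FALSE)
  tmB <- vapply(p$guide_core,
                function(g) melting_temperature(substr(g, 9, 14)), 0,
                USE.NAMES = FALSE)
  cfg <- sampling_config(n_reps = 15, subset_size = 13, seed = 3)
  # activity exactly linear in Tm(A) - Tm(B): the difference scheme is perfect
  act <- activities_from(p, 200 + (tmA - tmB))
  cc <- combined_region_correlation(p, act, c(2, 5), c(9, 14),
                                    "tm_difference", cfg)
  expect_equal(cc$train_combined_r, rep(1, 15), tolerance = 1e-9)
  expect_equal(cc$valid_combined_r, rep(1, 15), tolerance = 1e-9)
  # r_product can never exceed a factor with |r| < 1
  act2 <- activities_from(p, 60 - 1.2 * tmA + rep(c(5, -5), 13))
  cp <- combined_region_correlation(p, act2, c(2, 5), c(9, 14),
                                    "r_product", cfg)
  expect_true(all(cp$train_combined_r <= cp$train_single_r + 1e-12))
  expect_error(combined_region_correlation(p, act, c(2, 5), c(9, 14),
                                           "bogus", cfg))
})

test_that("count_subsets is exact", {
  expect_identical(count_subsets(26, 13), 10400600)
  expect_identical(count_subsets(7, 0), 1)
  expect_identical(count_subsets(10, 3), 120)
  # brute-force enumeration oracle at small n
  expect_identical(count_subsets(10, 3), nrow(t(utils::combn(10, 3))) + 0)
  expect_error(count_subsets(5, 6), "exceed")
  expect_error(count_subsets(-1, 0), "non-negative")
})
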