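toy_counts <- c(negative = 358, low = 100, medium = 300, high = 242)

test_that("deflection efficiency is the deflected fraction of all input", {
  expect_equal(deflection_efficiency(toy_counts), 0.642)
  expect_equal(deflection_efficiency(c(negative = 10, low = 0, medium = 0,
                                       high = 0)), 0)
  expect_equal(deflection_efficiency(c(negative = 0, low = 1, medium = 2,
                                       high = 3)), 1)
  expect_error(deflection_efficiency(c(negative = 0, low = 0, medium = 0,
                                       high = 0)), "all outlets are zero")
  expect_error(deflection_efficiency(c(negative = -1, low = 1, medium = 1,
                                       high = 1)), "non-negative")
  expect_error(deflection_efficiency(c(low = 1, medium = 1, high = 1)),
               "missing outlet")
})

test_that("outlet profile normalises the deflected fraction triplet", {
  p <- exo_profile(c(negative = 0, low = 100, medium = 300, high = 242))
  expect_equal(p$f_L, 100 / 642)
  expect_equal(p$f_M, 300 / 642)
  expect_equal(p$f_H, 242 / 642)
  expect_equal(p$f_L + p$f_M + p$f_H, 1)
  p1 <- exo_profile(c(negative = 5, low = 0, medium = 7, high = 0))
  expect_equal(p1$f_M, 1)
  # nothing deflected: D reported, fractions undefined
  p0 <- exo_profile(c(negative = 9, low = 0, medium = 0, high = 0))
  expect_equal(p0$D, 0)
  expect_true(is.na(p0$f_L))
})

test_that("profile invariants hold over random count vectors", {
  set.seed(31)
  for (i in 1:500) {
    x <- c(negative = rpois(1, 20), low = rpois(1, 10),
           medium = rpois(1, 10), high = rpois(1, 10))
    if (sum(x) == 0) next
    D <- deflection_efficiency(x)
    expect_gte(D, 0)
    expect_lte(D, 1)
    if (sum(x[-1]) > 0) {
      p <- exo_profile(x)
      expect_equal(p$f_L + p$f_M + p$f_H, 1)
      expect_equal(p$D, D)
    }
  }
})

test_that("expression score combines efficiency and profile as documented", {
  expect_equal(nanoepic_score(toy_counts), 142.6)
  expect_equal(nanoepic_score(c(negative = 7, low = 0, medium = 0, high = 0)), 0)
  expect_equal(nanoepic_score(c(negative = 0, low = 0, medium = 0, high = 50)),
               300)
  # scale invariance in the total count
  expect_equal(nanoepic_score(toy_counts * 1e6), nanoepic_score(toy_counts))
  expect_error(nanoepic_score(toy_counts, weights = c(1, 2)), "weights")
  expect_error(nanoepic_score(toy_counts, weights = c(-1, 2, 3)), "weights")
})

test_that("moving a vesicle to a higher outlet never lowers the score", {
  # exhaustive over all compositions of N = 10 into the four outlets
  N <- 10
  grid <- expand.grid(negative = 0:N, low = 0:N, medium = 0:N, high = 0:N)
  grid <- grid[rowSums(grid) == N, ]
  lev <- c("negative", "low", "medium", "high")
  for (i in seq_len(nrow(grid))) {
    x <- unlist(grid[i, ])
    s <- nanoepic_score(x)
    for (from in 1:3) {
      if (x[from] == 0) next
      y <- x
      y[from] <- y[from] - 1
      y[from + 1] <- y[from + 1] + 1
      expect_gte(nanoepic_score(y), s - 1e-12)
    }
  }
})

test_that("fold change is the after/before ratio with guarded zeros", {
  expect_equal(score_fold_change(142.6, 142.6), 1)
  expect_equal(score_fold_change(120, 0), 0)
  expect_lt(score_fold_change(120, 80), 1)  # responder-like decrease
  expect_error(score_fold_change(0, 50), "undefined ratio")
})

test_that("plateau model evaluates the saturating growth curve", {
  expect_equal(plateau_eval(printed_plateau, 0), -1945)
  expect_equal(plateau_eval(printed_plateau, 1e6), 2213)
  # hand value at x = 100: 2213 - 4158 exp(-0.8393)
  expect_equal(plateau_eval(printed_plateau, 100),
               2213 - 4158 * exp(-0.8393), tolerance = 1e-12)
  expect_error(plateau_eval(printed_plateau, -5), "x must be")
  expect_error(plateau_params(100, 200, 0.1), "y_max > y0")
  expect_error(plateau_params(200, 100, -1), "k must be")
})

test_that("plateau fitter recovers generating parameters from clean data", {
  x <- seq(0, 400, by = 25)
  y <- plateau_eval(printed_plateau, x)
  fit <- plateau_fit(x, y)
  expect_equal(fit$y_max, 2213, tolerance = 1e-6)
  expect_equal(fit$y0, -1945, tolerance = 1e-6)
  expect_equal(fit$k, 0.008393, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-6)
  expect_error(plateau_fit(x, rep(5, length(x))), "k unidentifiable")
  expect_error(plateau_fit(1:3, 1:3), "4")
})

test_that("synthetic cohorts lie on the curve at zero noise and partition", {
  cohort <- synth_cohort(30, printed_plateau, score_range = c(80, 400),
                         noise_sd = 0, seed = 17)
  expect_equal(cohort$volume, plateau_eval(printed_plateau, cohort$score))
  expect_identical(nrow(cohort), 30L)
  expect_identical(sum(table(cohort$response)), 30L)
  again <- synth_cohort(30, printed_plateau, score_range = c(80, 400),
                        noise_sd = 0, seed = 17)
  expect_identical(cohort, again)
  # volumes never negative when clipped
  noisy <- synth_cohort(50, printed_plateau, noise_sd = 300, seed = 18)
  expect_true(all(noisy$volume >= 0))
  expect_error(synth_cohort(3, printed_plateau), "n_subjects")
  expect_error(synth_cohort(10, printed_plateau, score_range = c(5, 2)),
               "score_range")
})
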