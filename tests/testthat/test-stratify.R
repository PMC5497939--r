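test_that("population summaries use the linear-interpolation quantile estimator", {
  s <- scale_scores(scores_frame(rnorm(100)))
  s$raw <- c(1, 2, 3, 4, 5, rep(0, 95))
  s$population <- c(rep("A", 5), rep("B", 95))
  s$scaled <- s$raw  # summarize the raw values directly via the scaled slot
  qt <- summarize_population(s)
  a <- qt[qt$population == "A", ]
  # hand-applied q(p) = x_(k) + g (x_(k+1) - x_(k)), k = floor(p(n-1)) + 1
  expect_equal(unlist(a[c("q20", "q40", "q60", "q80")], use.names = FALSE),
               c(1.8, 2.6, 3.4, 4.2))
  expect_equal(a$min, 1)
  expect_equal(a$max, 5)
  expect_true(a$ci_low <= a$mean && a$mean <= a$ci_high)

  b <- qt[qt$population == "B", ]  # constant scores collapse the summary
  expect_equal(unlist(b[c("min", "q20", "q40", "q60", "q80", "max", "mean")],
                      use.names = FALSE), rep(0, 7))
  expect_equal(b$ci_high - b$ci_low, 0)
})

test_that("quantiles are monotone, duplication-invariant, and shift with a constant", {
  set.seed(21)
  x <- rnorm(200)
  s <- scores_frame(x); s$scaled <- x
  qt <- summarize_population(s)
  qv <- unlist(qt[1, c("min", "q20", "q40", "q60", "q80", "max")],
               use.names = FALSE)
  expect_true(all(diff(qv) >= 0))

  s2 <- scores_frame(rep(x, each = 2)); s2$scaled <- rep(x, each = 2)
  qt2 <- summarize_population(s2)
  expect_equal(unlist(qt2[1, c("q20", "q40", "q60", "q80")]),
               unlist(qt[1, c("q20", "q40", "q60", "q80")]), tolerance = 1e-12)

  s3 <- scores_frame(x); s3$scaled <- x + 2.5
  qt3 <- summarize_population(s3)
  for (col in c("mean", "ci_low", "ci_high", "min", "q20", "q40", "q60",
                "q80", "max")) {
    expect_equal(qt3[[col]], qt[[col]] + 2.5, tolerance = 1e-12)
  }
})

test_that("undersized populations are rejected by name", {
  s <- scores_frame(1:10, population = c(rep("BIG", 7), rep("TINY", 3)))
  s$scaled <- s$raw
  expect_error(summarize_population(s), "TINY")
})

test_that("quintile assignment uses the boundary-to-lower convention", {
  set.seed(31)
  x <- rnorm(1000)
  s <- scores_frame(x, population = "REF"); s$scaled <- x
  qt <- summarize_population(s)
  th <- unlist(qt[1, c("q20", "q40", "q60", "q80")], use.names = FALSE)

  probe <- scores_frame(c(th[4], qt$max[1] + 1, th[1], qt$min[1] - 1),
                        population = "REF")
  probe$scaled <- probe$raw
  asg <- assign_quintiles(probe, qt, "REF")
  expect_equal(asg$quintile, c(4L, 5L, 1L, 1L))
  expect_error(assign_quintiles(probe, qt, "NOPE"), "unknown reference")
})

test_that("own-population quintiles hold a fifth of samples each", {
  set.seed(41)
  x <- rnorm(1000)
  s <- scores_frame(x, population = "REF"); s$scaled <- x
  qt <- summarize_population(s)
  counts <- table(assign_quintiles(s, qt, "REF")$quintile)
  expect_true(all(abs(counts - 200) <= 1))
})

test_that("cross-population transfer is uniform for self and extreme for separation", {
  set.seed(51)
  x <- rnorm(800)
  s <- scores_frame(c(x, x + 10),
                    population = rep(c("REF", "FAR"), each = 800),
                    sample_id = sprintf("s%04d", 1:1600))
  s$scaled <- s$raw
  qt <- summarize_population(s)
  self <- cross_population_shift(s, qt, "REF", "REF")
  expect_equal(sum(self), 1)
  expect_true(all(abs(self - 0.2) <= 1 / 800 + 1e-12))
  far <- cross_population_shift(s, qt, "REF", "FAR")
  expect_equal(unname(far), c(0, 0, 0, 0, 1))
  expect_error(cross_population_shift(s, qt, "REF", "NOPE"), "unknown target")
})

test_that("logistic OR recovery, null behaviour, and degenerate input", {
  set.seed(61)
  z <- rnorm(5000)
  s <- scores_frame(z); s$scaled <- z
  y <- simulate_phenotypes(s, true_or = 1.76, prevalence_target = 0.2,
                           seed = 62L)
  fit <- fit_prs_logistic(s, y)
  expect_true(fit$ci_low <= 1.76 && 1.76 <= fit$ci_high)

  y0 <- simulate_phenotypes(s, true_or = 1, prevalence_target = 0.2,
                            seed = 63L)
  fit0 <- fit_prs_logistic(s, y0)
  expect_true(fit0$ci_low <= 1 && 1 <= fit0$ci_high)

  expect_error(fit_prs_logistic(s, rep(1L, 5000)), "classes")
  expect_error(fit_prs_logistic(s, as.integer(z > 0)), "separation")
})
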