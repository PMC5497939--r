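test_that("population models validate their parameters", {
  pops <- data.frame(label = c("A", "B"), n = c(10L, 10L),
                     f = c(0.05, 0.05), delta = c(0, 0))
  expect_s3_class(population_model(10L, pops), "population_model")
  expect_error(population_model(10L, transform(pops, f = c(0, 0.5))), "f must")
  expect_error(population_model(10L, transform(pops, n = c(1L, 5L))), ">= 2")
  expect_error(population_model(10L, transform(pops, delta = c(-0.1, 0))),
               "delta")
  expect_error(population_model(10L, pops, ancestral_range = c(0, 0.5)),
               "ancestral_range")
  expect_error(population_model(10L, transform(pops, label = c("A", "A"))),
               "unique")
})

test_that("Balding-Nichols frequencies have the model's moments", {
  pops <- data.frame(label = c("LOW", "BN"), n = c(5L, 5L),
                     f = c(1e-6, 0.1), delta = c(0, 0))
  model <- population_model(10000L, pops, ancestral_range = c(0.45, 0.55),
                            seed = 71L)
  truth <- simulate_frequencies(model)

  # f -> 0 limit: per-population frequency collapses to the ancestral p
  expect_lt(max(abs(truth$pop_freqs[, "LOW"] - truth$ancestral)), 0.01)

  # E[p_pop] = p and Var[p_pop] = f p (1-p): Monte-Carlo over 10k SNPs
  dev <- truth$pop_freqs[, "BN"] - truth$ancestral
  expect_lt(abs(mean(dev)), 3 * sd(dev) / sqrt(10000))
  v <- dev^2
  target <- mean(0.1 * truth$ancestral * (1 - truth$ancestral))
  expect_lt(abs(mean(v) - target), 3 * sd(v) / sqrt(10000))
})

test_that("the directional shift moves risk-allele frequencies by delta", {
  pops <- data.frame(label = c("A", "B"), n = c(5L, 5L),
                     f = c(1e-6, 1e-6), delta = c(0, 0.05))
  model <- population_model(2000L, pops, ancestral_range = c(0.2, 0.8),
                            seed = 73L)
  truth <- simulate_frequencies(model)
  shift <- (truth$pop_freqs[, "B"] - truth$pop_freqs[, "A"]) *
    sign(truth$weights$weight)
  expect_equal(mean(shift), 0.05, tolerance = 1e-3)
  expect_true(all(truth$pop_freqs >= 0.01 & truth$pop_freqs <= 0.99))
})

test_that("HWE genotypes match binomial moments and are seed-deterministic", {
  pops <- data.frame(label = "P", n = 10000L, f = 1e-6, delta = 0)
  model <- population_model(5L, pops, ancestral_range = c(0.49, 0.51),
                            seed = 79L)
  truth <- simulate_frequencies(model)
  g <- simulate_genotypes(truth)
  mu <- colMeans(g$dosages)
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_true(all(abs(mu - 2 * truth$pop_freqs[, "P"]) < 3 * se + 0.01))

  g2 <- simulate_genotypes(truth)
  expect_identical(g$dosages, g2$dosages)

  # frequency 0.99 ceiling: essentially all dosages near 2
  pops1 <- data.frame(label = "Q", n = 50L, f = 1e-6, delta = 0.9)
  m1 <- population_model(20L, pops1, ancestral_range = c(0.5, 0.6),
                         weight_mean = 0.5, weight_sd = 0.01, seed = 83L)
  t1 <- simulate_frequencies(m1)
  expect_true(all(t1$pop_freqs[, "Q"] == 0.99))
  g1 <- simulate_genotypes(t1)
  expect_gt(mean(g1$dosages), 1.9)
})

test_that("analytic PRS moments match simulation", {
  # single SNP, w = 1, p = 0.5 -> mean 1, variance 0.5
  pops <- data.frame(label = "P", n = 2000L, f = 1e-6, delta = 0)
  m1 <- population_model(1L, pops, ancestral_range = c(0.499, 0.501),
                         weight_mean = 1, weight_sd = 1e-9, seed = 89L)
  t1 <- simulate_frequencies(m1)
  mo <- expected_prs_moments(t1, t1$weights, "P")
  expect_equal(mo$mean, 1, tolerance = 0.01)
  expect_equal(mo$variance, 0.5, tolerance = 0.01)

  zero <- t1
  zero$weights$weight <- 0
  expect_equal(expected_prs_moments(zero, zero$weights, "P"),
               list(mean = 0, variance = 0))

  # CLT check on a full population
  model <- two_pop_model(seed = 97L, n_snps = 500L, n = c(2000L, 2000L))
  sc <- scored_from_model(model)
  for (pop in c("REF", "TGT")) {
    mo <- expected_prs_moments(sc$truth, sc$truth$weights, pop)
    emp <- sc$scores$raw[sc$scores$population == pop]
    expect_lt(abs(mean(emp) - mo$mean), 4 * sqrt(mo$variance / 2000))
  }
})

test_that("simulated phenotypes hit the target prevalence and known OR", {
  sc <- scored_from_model(two_pop_model(seed = 101L, n_snps = 200L,
                                        n = c(2500L, 2500L)))
  y <- simulate_phenotypes(sc$scores, true_or = 1.76,
                           prevalence_target = 0.15, seed = 103L)
  se <- sqrt(0.15 * 0.85 / 5000)
  expect_lt(abs(mean(y) - 0.15), 3 * se)

  fit <- fit_prs_logistic(sc$scores, y)
  expect_true(fit$ci_low <= 1.76 && 1.76 <= fit$ci_high)

  y1 <- simulate_phenotypes(sc$scores, true_or = 1,
                            prevalence_target = 0.15, seed = 107L)
  fit1 <- fit_prs_logistic(sc$scores, y1)
  expect_true(fit1$ci_low <= 1 && 1 <= fit1$ci_high)

  expect_error(simulate_phenotypes(sc$scores, 1.5, prevalence_target = 0),
               "unattainable")
})

test_that("fixture perturbation fractions are exact by construction", {
  model <- two_pop_model(seed = 109L, n_snps = 1000L, n = c(30L, 30L))
  fx <- write_fixture(model, tempfile(), ref_effect_fraction = 0.2,
                      palindromic_fraction = 0.10, missing_fraction = 0.05)
  tab <- fx$weights_table
  r <- read_genotypes(fx$vcf, tab)
  h <- harmonize(r$genotypes, tab, log = r$log)
  expect_equal(sum(h$log$reason == "palindromic"), 100L)
  expect_equal(sum(h$log$reason == "not_in_vcf"), 50L)
  expect_equal(ncol(h$genotypes$dosages), 850L)

  clean <- write_fixture(two_pop_model(seed = 113L, n_snps = 200L,
                                       n = c(20L, 20L)), tempfile(),
                         ref_effect_fraction = 0, palindromic_fraction = 0,
                         missing_fraction = 0)
  r2 <- read_genotypes(clean$vcf, clean$weights_table)
  h2 <- harmonize(r2$genotypes, clean$weights_table, log = r2$log)
  expect_equal(nrow(h2$log), 0L)
})

test_that("the full pipeline is bit-reproducible under a seed", {
  model <- two_pop_model(seed = 127L, n_snps = 150L, n = c(25L, 25L))
  run <- function() {
    fx <- write_fixture(model, tempfile())
    tab <- orient_to_risk_increasing(fx$weights_table)
    r <- read_genotypes(fx$vcf, tab)
    r$genotypes <- attach_populations(r$genotypes, fx$pop_map)
    h <- harmonize(r$genotypes, tab, log = r$log)
    s <- scale_scores(compute_prs(h, tab))
    p <- tempfile(fileext = ".tsv")
    write_scores(s, p)
    readLines(p)
  }
  expect_identical(run(), run())
})
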