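test_that("PCA separates differentiated populations along PC1", {
  model <- two_pop_model(seed = 13L, n_snps = 2000L, n = c(100L, 100L),
                         f = c(0.2, 0.2))
  sc <- scored_from_model(model)
  pca <- genotype_pca(sc$genotypes, n_components = 3L)
  pc1 <- pca$scores[, 1L]
  pops <- sc$genotypes$populations
  mu <- tapply(pc1, pops, mean)
  pooled_sd <- sqrt(mean(tapply(pc1, pops, var)))
  separation <- abs(diff(mu)) / pooled_sd
  expect_gt(separation, 5)

  expect_true(all(diff(pca$explained_variance_fraction) <= 1e-12))
  expect_lte(sum(pca$explained_variance_fraction), 1 + 1e-12)
  dots <- crossprod(pca$scores)
  nrm <- sqrt(diag(dots))
  C <- dots / outer(nrm, nrm)
  expect_true(all(abs(C[upper.tri(C)]) < 1e-8))
})

test_that("PCA rejects invalid component counts and degenerate matrices", {
  X <- matrix(sample(0:2, 40, replace = TRUE), nrow = 8)
  g <- genotypes_from_matrix(X)
  expect_error(genotype_pca(g, n_components = 8L), "n_components")
  flat <- genotypes_from_matrix(matrix(1L, nrow = 6, ncol = 4))
  expect_error(genotype_pca(flat), "variance|monomorphic")
})

test_that("PCA scores are sample-order equivariant up to sign", {
  set.seed(17)
  X <- matrix(sample(0:2, 600, replace = TRUE), nrow = 30)
  g <- genotypes_from_matrix(X)
  p1 <- genotype_pca(g, 2L)
  perm <- sample(nrow(X))
  p2 <- genotype_pca(genotypes_from_matrix(X[perm, ]), 2L)
  for (k in 1:2) {
    a <- unname(p1$scores[perm, k]); b <- unname(p2$scores[, k])
    expect_true(isTRUE(all.equal(a, b, tolerance = 1e-8)) ||
                  isTRUE(all.equal(a, -b, tolerance = 1e-8)))
  }
})

test_that("PRS-PC1 correlation is exact for proportional scores and errors on constants", {
  model <- two_pop_model(seed = 19L, n_snps = 300L, n = c(80L, 80L))
  sc <- scored_from_model(model)
  pca <- genotype_pca(sc$genotypes, 1L, scope = "one_population",
                      population = "REF")
  s <- sc$scores
  idx <- match(rownames(pca$scores), s$sample_id)
  s$scaled[idx] <- pca$scores[, 1L]  # make the score proportional to PC1
  ct <- prs_pc1_correlation(s, sc$genotypes, "REF")
  expect_equal(abs(ct$r), 1, tolerance = 1e-10)
  expect_lt(ct$p_value, 1e-20)

  s$scaled[idx] <- 0
  expect_error(prs_pc1_correlation(s, sc$genotypes, "REF"), "constant")
})

test_that("top-weight selection orders by |weight| with lexicographic ties", {
  tab <- weight_table(c("rs3", "rs1", "rs2", "rs4"),
                      rep("G", 4), rep("A", 4),
                      beta = c(0.1, -0.5, 0.3, -0.3))
  top2 <- top_effect_snps(tab, 2L)
  expect_equal(top2$snp_id, c("rs1", "rs2"))  # |w| 0.5 then tie rs2 < rs4
  expect_equal(top_effect_snps(tab, 4L)$snp_id, c("rs1", "rs2", "rs4", "rs3"))
  expect_error(top_effect_snps(tab, 5L), "exceeds")
})

test_that("effect-allele frequencies are counted over non-missing dosages", {
  X <- matrix(c(0L, 1L, 2L,
                2L, 2L, 2L,
                1L, NA, 1L), nrow = 3,
              dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  g <- genotypes_from_matrix(X, populations = "A")
  tab <- weight_table(c("rs1", "rs2", "rs3", "rs9"), rep("G", 4),
                      rep("A", 4), beta = c(0.2, 0.1, 0.1, 0.4))
  expect_warning(fc <- compare_effect_allele_freqs(g, tab, "A", "A"), "rs9")
  expect_equal(fc$freq_a, c(3 / 6, 1, 2 / 4))
  expect_true(all(fc$freq_a >= 0 & fc$freq_a <= 1))
})

test_that("a directional risk-allele shift is recovered in frequency space", {
  model <- two_pop_model(seed = 23L, n_snps = 400L, n = c(400L, 400L),
                         f = c(0.001, 0.001), delta = c(0, 0.05))
  truth <- simulate_frequencies(model)
  g <- simulate_genotypes(truth)
  oriented <- orient_to_risk_increasing(truth$weights)
  top <- top_effect_snps(oriented, 20L)
  fc <- compare_effect_allele_freqs(g, top, "REF", "TGT")

  # oracle: realized truth frequencies of the risk allele
  idx <- match(top$snp_id, rownames(truth$pop_freqs))
  flip <- truth$weights$weight[idx] < 0
  pA <- truth$pop_freqs[idx, "REF"]; pA[flip] <- 1 - pA[flip]
  pB <- truth$pop_freqs[idx, "TGT"]; pB[flip] <- 1 - pB[flip]

  se <- sqrt(sum(pA * (1 - pA) / (2 * 400) + pB * (1 - pB) / (2 * 400))) / 20
  expect_lt(abs(mean(fc$freq_b - fc$freq_a) - mean(pB - pA)), 3 * se)
  expect_lt(abs(mean(fc$freq_b - fc$freq_a) - 0.05), 0.02)
})

test_that("undifferentiated populations show no mean score difference", {
  model <- two_pop_model(seed = 29L, n_snps = 500L, n = c(500L, 500L),
                         f = c(1e-4, 1e-4))
  sc <- scored_from_model(model)
  mu <- tapply(sc$scores$raw, sc$scores$population, mean)
  v <- tapply(sc$scores$raw, sc$scores$population, var)
  se <- sqrt(sum(v / 500))
  expect_lt(abs(diff(mu)), 4 * se)
})
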