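#' PCA of a model-SNP dosage matrix
#'
#' Principal component analysis of the genotype matrix using the standard
#' genotype normalization: each SNP column is centered by `2*p_hat` and
#' scaled by `sqrt(2*p_hat*(1-p_hat))`, where `p_hat` is the sample
#' counted-allele frequency, so that every SNP contributes comparable
#' variance. Missing dosages are mean-substituted before normalization
#' (scoring keeps its own missing-data policy). Monomorphic SNPs are
#' dropped (their normalization is undefined); if none remain the matrix
#' is degenerate and an error is raised. Each component's sign is fixed so
#' that its loading sum is non-negative.
#'
#' @param x a `prs_genotypes` or `prs_harmonized` object.
#' @param n_components number of components to return; must not exceed
#'   `min(samples - 1, SNPs)`.
#' @param scope `all_samples` or `one_population` (with `population`
#'   naming it); per-population PCA is what the per-population PRS-PC1
#'   correlation uses.
#' @param population population label when `scope = "one_population"`.
#' @return A `prs_pca` list: `scores` (samples x components),
#'   `explained_variance_fraction`, `snp_ids`, `loadings`.
#' @export
genotype_pca <- function(x, n_components = 2L,
                         scope = c("all_samples", "one_population"),
                         population = NULL) {
  scope <- match.arg(scope)
  g <- if (inherits(x, "prs_harmonized")) x$genotypes else x
  stopifnot(inherits(g, "prs_genotypes"))
  X <- g$dosages * 1.0
  if (scope == "one_population") {
    if (is.null(population)) stop("scope 'one_population' needs a population")
    if (is.null(g$populations)) stop("genotypes carry no population labels")
    X <- X[g$populations == population, , drop = FALSE]
    if (!nrow(X)) stop("no samples in population '", population, "'")
  }
  n <- nrow(X)
  if (n_components > min(n - 1L, ncol(X))) {
    stop("n_components exceeds min(samples - 1, SNPs)")
  }
  miss <- is.na(X)
  if (any(miss)) {
    fill <- colMeans(X, na.rm = TRUE)
    fill[!is.finite(fill)] <- 0
    ij <- which(miss, arr.ind = TRUE)
    X[miss] <- fill[ij[, 2L]]
  }
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic; PCA undefined")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  Xs <- sweep(X, 2L, 2 * p, "-")
  Xs <- sweep(Xs, 2L, sqrt(2 * p * (1 - p)), "/")
  pr <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  if (total_var == 0) stop("genotype matrix has no variance; PCA undefined")
  k <- seq_len(n_components)
  load <- pr$rotation[, k, drop = FALSE]
  sc <- pr$x[, k, drop = FALSE]
  flip <- colSums(load) < 0
  load[, flip] <- -load[, flip]
  sc[, flip] <- -sc[, flip]
  structure(list(scores = sc,
                 explained_variance_fraction = pr$sdev[k]^2 / total_var,
                 snp_ids = colnames(X),
                 loadings = load),
            class = "prs_pca")
}

#' Correlation between PRS and the population's own first PC
#'
#' Recomputes the PCA on the given population's samples only and reports
#' the Pearson correlation between its PC1 and the scaled PRS, with the
#' two-sided t-test p-value. Because a PC's sign is an arbitrary
#' convention of the eigen-solver, `|r|` is the meaningful magnitude; the
#' signed value is returned as computed under this package's sign fix.
#' A strong correlation means that within-population genetic structure
#' leaks into the score, so misclassifying an individual's population
#' also biases their risk estimate.
#'
#' @param scores a `prs_scores` data frame with `scaled` filled.
#' @param x a `prs_genotypes` or `prs_harmonized` object with population
#'   labels.
#' @param population label of the population to analyse (>= 3 samples).
#' @return List: `r`, `p_value`, `n`.
#' @export
prs_pc1_correlation <- function(scores, x, population) {
  g <- if (inherits(x, "prs_harmonized")) x$genotypes else x
  stopifnot(inherits(g, "prs_genotypes"))
  if (is.null(g$populations)) stop("genotypes carry no population labels")
  samples <- g$sample_ids[g$populations == population]
  if (length(samples) < 3L) {
    stop("population '", population, "' has fewer than 3 samples")
  }
  pca <- genotype_pca(g, n_components = 1L, scope = "one_population",
                      population = population)
  pc1 <- pca$scores[, 1L]
  idx <- match(rownames(pca$scores), scores$sample_id)
  if (anyNA(idx)) stop("scores are missing sample(s) of population '", population, "'")
  z <- scores$scaled[idx]
  if (anyNA(z)) stop("scaled scores required; run scale_scores() first")
  if (stats::sd(z) == 0 || stats::sd(pc1) == 0) {
    stop("constant PRS or PC1 in population '", population, "'")
  }
  ct <- stats::cor.test(z, pc1)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(z))
}

#' Top-weight SNPs of a model
#'
#' Returns the `k` records with the largest absolute weight, ties broken
#' by lexicographic SNP ID. Absolute weight is used as the ranking proxy
#' for the "most contributing" SNPs; the discovery GWAS z-scores are not
#' part of a weight file and need not order SNPs identically.
#'
#' @param table a [weight_table()].
#' @param k number of records, `k <= n_snps(table)`.
#' @return A [weight_table()] subset of `k` records.
#' @export
top_effect_snps <- function(table, k) {
  if (k > nrow(table)) stop("k exceeds the number of SNPs in the table")
  ord <- order(-abs(table$weight), table$snp_id)
  new_weight_table(as.data.frame(table)[ord[seq_len(k)], ],
                   attr(table, "model_name"))
}

#' Effect-allele frequencies of selected SNPs in two populations
#'
#' Computes, per SNP and per population, the effect-allele frequency
#' `sum(dosage) / (2 * n_non_missing)`. The weight subset should be
#' oriented risk-increasing (see [orient_to_risk_increasing()]) so that
#' "effect allele" means "the allele that raises the score" for every SNP
#' and the two populations' frequencies are directly comparable. SNPs of
#' the subset absent from the harmonized matrix are skipped with a
#' warning.
#'
#' @param h a `prs_harmonized` object (or effect-counting
#'   `prs_genotypes`) with population labels.
#' @param subset a [weight_table()] of the SNPs to compare (e.g. from
#'   [top_effect_snps()]).
#' @param popA,popB population labels.
#' @return A `prs_freq_comparison` data frame: `snp_id`, `weight`,
#'   `freq_a`, `freq_b`, with the population names in attributes
#'   `popA`/`popB`.
#' @export
compare_effect_allele_freqs <- function(h, subset, popA, popB) {
  g <- if (inherits(h, "prs_harmonized")) h$genotypes else h
  stopifnot(inherits(g, "prs_genotypes"))
  if (!identical(g$counting, "effect")) {
    stop("dosages must count the effect allele; run harmonize() first")
  }
  if (is.null(g$populations)) stop("genotypes carry no population labels")
  present <- subset$snp_id %in% colnames(g$dosages)
  if (any(!present)) {
    warning("skipping SNP(s) absent from the harmonized set: ",
            paste(subset$snp_id[!present], collapse = ", "))
  }
  sub <- subset[present, , drop = FALSE]
  # the dosage columns count g$alt; when the subset's effect allele is the
  # column's other allele, the effect-allele frequency is the complement
  counted <- g$alt[sub$snp_id]
  other <- g$ref[sub$snp_id]
  flip <- sub$effect_allele == other & sub$other_allele == counted
  mismatch <- !flip & !(sub$effect_allele == counted & sub$other_allele == other)
  if (any(mismatch)) {
    stop("allele pair of SNP(s) ", paste(sub$snp_id[mismatch], collapse = ", "),
         " does not match the genotype columns")
  }
  pop_freq <- function(pop) {
    rows <- g$populations == pop
    if (!any(rows)) stop("unknown population '", pop, "'")
    d <- g$dosages[rows, sub$snp_id, drop = FALSE]
    fq <- colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
    fq[flip] <- 1 - fq[flip]
    fq
  }
  out <- data.frame(snp_id = sub$snp_id,
                    weight = sub$weight,
                    freq_a = unname(pop_freq(popA)),
                    freq_b = unname(pop_freq(popB)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("prs_freq_comparison", "data.frame"),
            popA = popA, popB = popB)
}
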