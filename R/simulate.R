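#' Define a multi-population simulation model
#'
#' The simulator emulates the data a portability study needs: K
#' populations diverged from a common ancestral allele-frequency spectrum
#' under the Balding-Nichols model (per-population differentiation `f`,
#' playing the role of F_ST against the ancestral pool), Hardy-Weinberg
#' genotypes in linkage equilibrium, a weight vector with effects of both
#' signs, and an optional deterministic shift `delta` of each risk-allele
#' frequency that reproduces, with known truth, the directional
#' between-population score shifts seen in real super-population panels.
#'
#' @param n_snps number of model SNPs.
#' @param populations data frame with columns `label`, `n` (sample size,
#'   >= 2), `f` (Balding-Nichols differentiation, in (0,1)), `delta`
#'   (risk-allele frequency shift, >= 0).
#' @param ancestral_range interval within (0,1) for the uniform ancestral
#'   frequencies; bounded away from 0/1 so no SNP starts near fixation.
#' @param weight_mean,weight_sd normal distribution of the effect sizes
#'   `beta` (log-odds per allele). Defaults (0, 0.05) give the small
#'   both-sign effects typical of genome-wide score models.
#' @param pi_range optional interval in \[0,1\]; when given, per-SNP
#'   shrinkage multipliers `pi` are drawn uniformly from it and the model
#'   is double-weighted.
#' @param seed integer seed; the whole pipeline is bit-reproducible under
#'   it.
#' @return A `population_model` list.
#' @export
population_model <- function(n_snps, populations,
                             ancestral_range = c(0.1, 0.9),
                             weight_mean = 0, weight_sd = 0.05,
                             pi_range = NULL, seed = 1L) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  req <- c("label", "n", "f", "delta")
  if (!all(req %in% names(populations))) {
    stop("populations must have columns: ", paste(req, collapse = ", "))
  }
  if (n_snps < 1L) stop("n_snps must be positive")
  if (any(populations$n < 2L)) stop("population sample sizes must be >= 2")
  if (any(populations$f <= 0 | populations$f >= 1)) {
    stop("all f must lie strictly in (0, 1)")
  }
  if (any(populations$delta < 0)) stop("delta must be >= 0")
  if (ancestral_range[1] < 0.01 || ancestral_range[2] > 0.99 ||
      ancestral_range[1] >= ancestral_range[2]) {
    stop("ancestral_range must be an interval within [0.01, 0.99]")
  }
  if (!is.null(pi_range) &&
      (pi_range[1] < 0 || pi_range[2] > 1 || pi_range[1] > pi_range[2])) {
    stop("pi_range must be an interval within [0, 1]")
  }
  if (anyDuplicated(populations$label)) stop("population labels must be unique")
  structure(list(n_snps = as.integer(n_snps),
                 populations = populations,
                 ancestral_range = ancestral_range,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 pi_range = pi_range,
                 seed = as.integer(seed)),
            class = "population_model")
}

# random non-palindromic allele pairs (effect/other), e.g. A/G, C/T
draw_allele_pairs <- function(m) {
  pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                 c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))
  pairs[sample.int(nrow(pairs), m, replace = TRUE), , drop = FALSE]
}

#' Draw ancestral and per-population allele frequencies plus true weights
#'
#' Ancestral effect-allele frequencies are uniform on the model's range.
#' Each population's frequency is drawn from the Balding-Nichols
#' distribution `Beta(p(1-f)/f, (1-p)(1-f)/f)`, which has mean `p` and
#' variance `f * p * (1-p)`. For populations with `delta > 0` the
#' frequency of the risk allele (the effect allele when the weight is
#' positive, the other allele when negative) is then moved toward the
#' risk allele by `delta` and clipped to \[0.01, 0.99\] — a deterministic
#' shift that makes the induced between-population score difference
#' analytically available (`2 * delta * sum(|w|)` for risk-increasing
#' weights). The clipping also keeps SNPs polymorphic, which genotype
#' PCA normalization requires.
#'
#' @param model a [population_model()].
#' @return A `prs_truth` list: `ancestral` (per-SNP effect-allele
#'   frequency), `pop_freqs` (SNPs x populations matrix), `weights` (a
#'   [weight_table()] with random non-palindromic allele pairs), `model`.
#' @export
simulate_frequencies <- function(model) {
  stopifnot(inherits(model, "population_model"))
  set.seed(model$seed)
  m <- model$n_snps
  p <- stats::runif(m, model$ancestral_range[1], model$ancestral_range[2])
  beta <- stats::rnorm(m, model$weight_mean, model$weight_sd)
  pi <- if (is.null(model$pi_range)) NULL else
    stats::runif(m, model$pi_range[1], model$pi_range[2])
  alleles <- draw_allele_pairs(m)
  tab <- weight_table(sprintf("rs%06d", seq_len(m)),
                      alleles[, 1L], alleles[, 2L], beta, pi,
                      model_name = "synthetic")
  K <- nrow(model$populations)
  pf <- matrix(NA_real_, m, K,
               dimnames = list(tab$snp_id, model$populations$label))
  risk_dir <- sign(tab$weight)
  for (k in seq_len(K)) {
    f <- model$populations$f[k]
    pk <- stats::rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    delta <- model$populations$delta[k]
    if (delta > 0) pk <- pk + delta * risk_dir
    pf[, k] <- pmin(pmax(pk, 0.01), 0.99)
  }
  structure(list(ancestral = stats::setNames(p, tab$snp_id),
                 pop_freqs = pf, weights = tab, model = model),
            class = "prs_truth")
}

#' Simulate HWE genotypes from a frequency truth set
#'
#' Dosages of the effect allele are drawn `Binomial(2, p_pop)`
#' independently per SNP and per sample (Hardy-Weinberg, linkage
#' equilibrium). Deterministic under the model seed: the same model gives
#' bit-identical matrices on every call.
#'
#' @param truth a `prs_truth` from [simulate_frequencies()].
#' @return A `prs_genotypes` object with population labels attached and
#'   dosages counting the effect allele (`counting = "effect"`), ready
#'   for [compute_prs()] directly or for [write_fixture()].
#' @export
simulate_genotypes <- function(truth) {
  stopifnot(inherits(truth, "prs_truth"))
  model <- truth$model
  set.seed(model$seed + 1L)
  m <- model$n_snps
  mats <- vector("list", nrow(model$populations))
  pops <- character(0)
  for (k in seq_len(nrow(model$populations))) {
    nk <- model$populations$n[k]
    label <- model$populations$label[k]
    # column-major fill: first nk draws belong to SNP 1, and so on
    mats[[k]] <- matrix(stats::rbinom(nk * m, 2L, rep(truth$pop_freqs[, k], each = nk)),
                        nrow = nk, ncol = m)
    rownames(mats[[k]]) <- sprintf("%s_%04d", label, seq_len(nk))
    pops <- c(pops, rep(label, nk))
  }
  X <- do.call(rbind, mats)
  colnames(X) <- truth$weights$snp_id
  new_prs_genotypes(X,
                    ref = stats::setNames(truth$weights$other_allele,
                                          truth$weights$snp_id),
                    alt = stats::setNames(truth$weights$effect_allele,
                                          truth$weights$snp_id),
                    populations = stats::setNames(pops, rownames(X)),
                    counting = "effect")
}

#' Analytic raw-PRS mean and variance for a population
#'
#' Under Hardy-Weinberg and linkage equilibrium the raw score of a sample
#' from a population with effect-allele frequencies `p_i` has
#' `mean = sum_i 2 w_i p_i` and
#' `variance = sum_i 2 w_i^2 p_i (1 - p_i)` — the closed-form oracle for
#' simulated between-population distribution shifts.
#'
#' The table may be allele-reoriented (see [orient_to_risk_increasing()]):
#' records whose effect allele is the truth's other allele use the
#' complementary frequency `1 - p`.
#'
#' @param truth a `prs_truth` from [simulate_frequencies()].
#' @param table a [weight_table()] aligned to the truth's SNPs (a subset
#'   is allowed).
#' @param population population label in the truth set.
#' @return List: `mean`, `variance`.
#' @export
expected_prs_moments <- function(truth, table, population) {
  stopifnot(inherits(truth, "prs_truth"))
  if (!population %in% colnames(truth$pop_freqs)) {
    stop("unknown population '", population, "'")
  }
  idx <- match(table$snp_id, rownames(truth$pop_freqs))
  if (anyNA(idx)) stop("weight table names SNP(s) absent from the truth set")
  p <- truth$pop_freqs[idx, population]
  tt <- truth$weights[match(table$snp_id, truth$weights$snp_id), ]
  swapped <- table$effect_allele == tt$other_allele &
    table$other_allele == tt$effect_allele
  p[swapped] <- 1 - p[swapped]
  w <- table$weight
  list(mean = sum(2 * w * p),
       variance = sum(2 * w^2 * p * (1 - p)))
}

#' Simulate a binary phenotype from scaled scores under a known odds ratio
#'
#' Case probability follows the logistic model
#' `P(case) = plogis(alpha + log(true_or) * scaled_PRS)`, with the
#' intercept `alpha` solved numerically so the mean case probability
#' equals `prevalence_target`. With `true_or = 1` the phenotype is
#' independent of the score.
#'
#' @param scores a `prs_scores` data frame with `scaled` filled.
#' @param true_or true odds ratio per scaled-PRS unit.
#' @param prevalence_target target mean case probability, in (0, 1).
#' @param seed integer seed for the Bernoulli draws.
#' @return Integer 0/1 vector, one per sample in score order.
#' @export
simulate_phenotypes <- function(scores, true_or, prevalence_target = 0.1,
                                seed = 1L) {
  z <- scores$scaled
  if (anyNA(z)) stop("scaled scores required; run scale_scores() first")
  if (prevalence_target <= 0 || prevalence_target >= 1) {
    stop("unattainable prevalence: target must lie strictly in (0, 1)")
  }
  b <- log(true_or)
  froot <- function(a) mean(stats::plogis(a + b * z)) - prevalence_target
  alpha <- tryCatch(stats::uniroot(froot, c(-50, 50))$root,
                    error = function(e) stop("unattainable prevalence for this score distribution"))
  set.seed(seed)
  stats::rbinom(length(z), 1L, stats::plogis(alpha + b * z))
}

#' Write a complete on-disk fixture: VCF, weights, population map, truth
#'
#' Materializes a simulated cohort as the files the file-based pipeline
#' consumes, deliberately exercising every harmonization path:
#' \itemize{
#'   \item a configurable fraction of SNPs is rewritten as palindromic
#'     A/T or C/G pairs (consistently in the VCF and the weight table),
#'     exercising the strand-ambiguity filter;
#'   \item a configurable fraction is written with the effect allele as
#'     VCF REF (so the written ALT dosage is `2 - effect dosage`),
#'     exercising the orientation flip;
#'   \item a configurable fraction is omitted from the VCF entirely,
#'     exercising `not_in_vcf` logging.
#' }
#' The three groups are disjoint, so the exclusion-log counts are exact
#' by construction. Reading the fixture back through [read_genotypes()]
#' and [harmonize()] recovers the simulated effect-allele dosage matrix
#' exactly (minus the palindromic and omitted SNPs).
#'
#' @param model a [population_model()].
#' @param out_dir output directory (created if absent).
#' @param ref_effect_fraction fraction of SNPs written with effect allele
#'   as REF.
#' @param palindromic_fraction fraction of SNPs rewritten palindromic.
#' @param missing_fraction fraction of SNPs omitted from the VCF.
#' @return List of paths (`vcf`, `weights`, `pop_map`, `truth_tsv`) plus the
#'   in-memory `truth` object, the (possibly reallelated) `weights_table`,
#'   the simulated `genotypes`, and the index vectors of the three
#'   perturbation groups.
#' @export
write_fixture <- function(model, out_dir, ref_effect_fraction = 0.3,
                          palindromic_fraction = 0.1,
                          missing_fraction = 0.05) {
  stopifnot(inherits(model, "population_model"))
  fr <- c(ref_effect_fraction, palindromic_fraction, missing_fraction)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("perturbation fractions must be non-negative and sum to at most 1")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- simulate_frequencies(model)
  geno <- simulate_genotypes(truth)
  tab <- truth$weights
  m <- model$n_snps

  set.seed(model$seed + 2L)
  n_pal <- round(palindromic_fraction * m)
  n_miss <- round(missing_fraction * m)
  n_ref <- round(ref_effect_fraction * m)
  perm <- sample.int(m)
  idx_pal <- sort(perm[seq_len(n_pal)])
  idx_miss <- sort(perm[n_pal + seq_len(n_miss)])
  idx_ref <- sort(perm[n_pal + n_miss + seq_len(n_ref)])

  if (n_pal) {
    pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    pick <- pal_pairs[sample.int(4L, n_pal, replace = TRUE), , drop = FALSE]
    tab$effect_allele[idx_pal] <- pick[, 1L]
    tab$other_allele[idx_pal] <- pick[, 2L]
    # keep the truth's allele letters in step with the written table
    truth$weights <- tab
  }

  # VCF orientation: ALT = effect allele by default; flipped for idx_ref
  ref_al <- tab$other_allele
  alt_al <- tab$effect_allele
  dos_alt <- geno$dosages
  if (n_ref) {
    ref_al[idx_ref] <- tab$effect_allele[idx_ref]
    alt_al[idx_ref] <- tab$other_allele[idx_ref]
    dos_alt[, idx_ref] <- 2L - dos_alt[, idx_ref]
  }
  in_vcf <- setdiff(seq_len(m), idx_miss)

  paths <- list(vcf = file.path(out_dir, "genotypes.vcf"),
                weights = file.path(out_dir, "weights.tsv"),
                pop_map = file.path(out_dir, "populations.tsv"),
                truth_tsv = file.path(out_dir, "truth.tsv"))
  write_vcf(paths$vcf,
            snp_ids = tab$snp_id[in_vcf],
            ref = ref_al[in_vcf], alt = alt_al[in_vcf],
            dosage_alt = dos_alt[, in_vcf, drop = FALSE])
  write_weights(tab, paths$weights)
  write_tsv(data.frame(sample_id = geno$sample_ids,
                       population = unname(geno$populations),
                       stringsAsFactors = FALSE),
            paths$pop_map)
  truth_df <- data.frame(snp_id = tab$snp_id,
                         ancestral = fmt_double(unname(truth$ancestral)),
                         stringsAsFactors = FALSE)
  for (lab in colnames(truth$pop_freqs)) {
    truth_df[[paste0("freq_", lab)]] <- fmt_double(truth$pop_freqs[, lab])
  }
  write_tsv(truth_df, paths$truth_tsv)

  c(paths, list(truth = truth, weights_table = tab, genotypes = geno,
                idx_palindromic = idx_pal, idx_ref_effect = idx_ref,
                idx_missing = idx_miss))
}

# minimal VCF 4.2 writer for simulated biallelic SNPs (GT only, diploid)
write_vcf <- function(path, snp_ids, ref, alt, dosage_alt) {
  samples <- rownames(dosage_alt)
  gt_codes <- c("0/0", "0/1", "1/1")
  G <- matrix(gt_codes[t(dosage_alt) + 1L], nrow = ncol(dosage_alt))
  fixed <- paste("1", seq_along(snp_ids), snp_ids, ref, alt,
                 ".", "PASS", ".", "GT", sep = "\t")
  geno_part <- do.call(paste, c(as.data.frame(G, stringsAsFactors = FALSE),
                                list(sep = "\t")))
  header <- c("##fileformat=VCFv4.2",
              "##source=prsport-simulator",
              "##contig=<ID=1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, paste(fixed, geno_part, sep = "\t")), path)
  invisible(path)
}
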