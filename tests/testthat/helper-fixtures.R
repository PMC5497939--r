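# shared builders for simulated cohorts and hand-written inputs

two_pop_model <- function(seed = 42L, n_snps = 300L,
                          n = c(60L, 60L), f = c(0.01, 0.01),
                          delta = c(0, 0), labels = c("REF", "TGT"), ...) {
  population_model(
    n_snps,
    data.frame(label = labels, n = n, f = f, delta = delta,
               stringsAsFactors = FALSE),
    seed = seed, ...)
}

scored_from_model <- function(model) {
  truth <- simulate_frequencies(model)
  genotypes <- simulate_genotypes(truth)
  scores <- scale_scores(compute_prs(genotypes, truth$weights))
  list(truth = truth, genotypes = genotypes, scores = scores)
}

# a prs_scores frame from given raw values (bypassing genotypes)
scores_frame <- function(raw, population = "POP",
                         sample_id = sprintf("s%04d", seq_along(raw))) {
  structure(data.frame(sample_id = sample_id,
                       population = rep_len(population, length(raw)),
                       raw = raw, scaled = NA_real_,
                       n_snps_used = 0L, stringsAsFactors = FALSE),
            class = c("prs_scores", "data.frame"))
}

# dosage matrix (samples x snps, effect-allele counts) as prs_genotypes
genotypes_from_matrix <- function(X, populations = NULL,
                                  effect = rep("G", ncol(X)),
                                  other = rep("A", ncol(X))) {
  if (is.null(rownames(X))) rownames(X) <- sprintf("s%04d", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("rs%04d", seq_len(ncol(X)))
  if (!is.null(populations)) {
    populations <- stats::setNames(rep_len(populations, nrow(X)), rownames(X))
  }
  prsport:::new_prs_genotypes(
    X,
    ref = stats::setNames(other, colnames(X)),
    alt = stats::setNames(effect, colnames(X)),
    populations = populations, counting = "effect")
}

tmp_weights_file <- function(df) {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}

# hand-written VCF: gt is a variants x samples character matrix of GT strings
write_mini_vcf <- function(ids, ref, alt, gt,
                           samples = sprintf("S%d", seq_len(ncol(gt)))) {
  p <- tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2", "##contig=<ID=1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- paste("1", seq_along(ids), ids, ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), p)
  p
}

# brute-force scoring oracle: explicit per-sample, per-SNP double loop
loop_prs <- function(X, w) {
  out <- numeric(nrow(X))
  for (j in seq_len(nrow(X))) {
    acc <- 0
    for (i in seq_len(ncol(X))) acc <- acc + w[i] * X[j, i]
    out[j] <- acc
  }
  out
}
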