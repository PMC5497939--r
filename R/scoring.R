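#' Compute raw polygenic risk scores
#'
#' The raw score of sample j is `sum_i w_i * X_ij`, the weighted count of
#' effect alleles over all retained model SNPs. Missing dosages are
#' substituted per `missing_policy`: `mean_dosage` (default) substitutes
#' the SNP's pooled mean dosage across all samples, matching the default
#' of the standard command-line scoring tools; `zero` substitutes 0;
#' `drop_snp_for_sample` omits the term. The latter two are numerically
#' identical for the sum but are kept distinct for documentation of
#' intent. `n_snps_used` records, per sample, how many SNPs contributed a
#' called genotype.
#'
#' @param x a `prs_harmonized` object (or a `prs_genotypes` object whose
#'   dosages already count the effect allele, e.g. from
#'   [simulate_genotypes()]).
#' @param table the [weight_table()] providing weights for every column.
#' @param missing_policy how to handle missing dosages.
#' @return A `prs_scores` data frame: `sample_id`, `population`, `raw`,
#'   `scaled` (NA until [scale_scores()]), `n_snps_used`.
#' @export
compute_prs <- function(x, table,
                        missing_policy = c("mean_dosage", "zero",
                                           "drop_snp_for_sample")) {
  missing_policy <- match.arg(missing_policy)
  g <- if (inherits(x, "prs_harmonized")) x$genotypes else x
  stopifnot(inherits(g, "prs_genotypes"))
  if (!identical(g$counting, "effect")) {
    stop("dosages must count the effect allele; run harmonize() first")
  }
  X <- g$dosages
  if (ncol(X) == 0L) stop("no SNPs left to score")
  w <- table$weight[match(colnames(X), table$snp_id)]
  if (anyNA(w)) {
    stop("weight table lacks weight(s) for column(s): ",
         paste(utils::head(colnames(X)[is.na(w)], 5L), collapse = ", "))
  }
  X <- X * 1.0
  miss <- is.na(X)
  n_used <- ncol(X) - rowSums(miss)
  if (any(miss)) {
    fill <- switch(missing_policy,
                   mean_dosage = colMeans(X, na.rm = TRUE),
                   zero = ,
                   drop_snp_for_sample = rep(0, ncol(X)))
    fill[!is.finite(fill)] <- 0  # SNPs missing in every sample
    ij <- which(miss, arr.ind = TRUE)
    X[miss] <- fill[ij[, 2L]]
  }
  raw <- drop(X %*% w)
  pops <- if (is.null(g$populations)) rep(NA_character_, nrow(X)) else
    unname(g$populations[rownames(X)])
  s <- data.frame(sample_id = rownames(X),
                  population = pops,
                  raw = unname(raw),
                  scaled = NA_real_,
                  n_snps_used = unname(n_used),
                  stringsAsFactors = FALSE)
  structure(s, class = c("prs_scores", "data.frame"),
            missing_policy = missing_policy)
}

#' Scale scores over the pooled sample set
#'
#' Standardizes the raw scores as z-scores over **all** samples pooled
#' across populations — never per population — so that distribution shifts
#' between populations stay visible on a common axis. The standard
#' deviation uses the n-1 denominator.
#'
#' @param scores a `prs_scores` data frame from [compute_prs()].
#' @return The same data frame with the `scaled` column filled; pooled
#'   mean 0 and SD 1.
#' @export
scale_scores <- function(scores) {
  stopifnot(inherits(scores, "prs_scores"))
  if (nrow(scores) < 2L) stop("scaling requires at least 2 samples")
  s <- stats::sd(scores$raw)
  if (!is.finite(s) || s == 0) {
    stop("raw scores have zero variance; cannot scale")
  }
  scores$scaled <- (scores$raw - mean(scores$raw)) / s
  scores
}

#' Write scores as TSV
#' @param scores a `prs_scores` data frame.
#' @param path output path.
#' @export
write_scores <- function(scores, path) {
  out <- data.frame(sample_id = scores$sample_id,
                    population = scores$population,
                    raw = fmt_double(scores$raw),
                    scaled = fmt_double(scores$scaled),
                    n_snps_used = scores$n_snps_used,
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read scores written by [write_scores()]
#' @param path path to a scores TSV.
#' @return A `prs_scores` data frame.
#' @export
read_scores <- function(path) {
  df <- read_tsv(path)
  df$raw <- as.numeric(df$raw)
  df$scaled <- as.numeric(df$scaled)
  structure(df, class = c("prs_scores", "data.frame"))
}

#' @export
print.prs_scores <- function(x, ...) {
  cat(sprintf("PRS scores for %d samples (%s)\n", nrow(x),
              if (all(is.na(x$scaled))) "raw only" else "pooled-scaled"))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
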