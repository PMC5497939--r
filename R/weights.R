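#' Construct a PRS weight table
#'
#' A weight table is the polygenic score model itself: one row per SNP with
#' the effect allele whose dosage is weighted, the other allele, the GWAS
#' effect size `beta` (log-odds per effect-allele copy), an optional
#' shrinkage multiplier `pi` in \[0, 1\], and the final per-SNP weight
#' `weight`. Single-weighted models (CHD-style scores) use `weight = beta`;
#' double-weighted models (T2D-style scores, where `pi` damps winner's-curse
#' inflation of selected effect sizes) use `weight = beta * pi`.
#'
#' @param snp_id character vector of unique SNP identifiers (rsID-style).
#' @param effect_allele,other_allele single bases in `A/C/G/T`; the effect
#'   allele is the one counted by the dosage.
#' @param beta numeric effect sizes (log odds per effect allele).
#' @param pi optional numeric shrinkage multipliers in \[0, 1\]. When given,
#'   the table is double-weighted.
#' @param model_name label carried through outputs.
#' @return A `weight_table`: a data frame with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `beta`, `pi`, `weight`.
#' @examples
#' weight_table(c("rs1", "rs2"), c("A", "C"), c("G", "T"), beta = c(0.3, -0.1))
#' @export
weight_table <- function(snp_id, effect_allele, other_allele, beta,
                         pi = NULL, model_name = "model") {
  df <- data.frame(snp_id = as.character(snp_id),
                   effect_allele = toupper(as.character(effect_allele)),
                   other_allele = toupper(as.character(other_allele)),
                   beta = as.numeric(beta),
                   stringsAsFactors = FALSE)
  if (is.null(pi)) {
    df$pi <- NA_real_
    df$weight <- df$beta
  } else {
    df$pi <- as.numeric(pi)
    df$weight <- df$beta * df$pi
  }
  validate_weight_table(df)
  new_weight_table(df, model_name)
}

new_weight_table <- function(df, model_name) {
  rownames(df) <- NULL
  structure(df, class = c("weight_table", "data.frame"),
            model_name = model_name)
}

validate_weight_table <- function(df) {
  bad <- !(df$effect_allele %in% BASES) | !(df$other_allele %in% BASES)
  if (any(bad)) {
    stop("non-ACGT allele for SNP(s): ",
         paste(utils::head(df$snp_id[bad], 5L), collapse = ", "))
  }
  same <- df$effect_allele == df$other_allele
  if (any(same)) {
    stop("effect and other allele identical for SNP(s): ",
         paste(utils::head(df$snp_id[same], 5L), collapse = ", "))
  }
  dup <- duplicated(df$snp_id)
  if (any(dup)) {
    stop("duplicate snp_id: ",
         paste(unique(df$snp_id[dup]), collapse = ", "))
  }
  pv <- df$pi[!is.na(df$pi)]
  if (length(pv) && any(pv < 0 | pv > 1)) stop("pi values must lie in [0, 1]")
  invisible(df)
}

#' Number of SNPs in a weight table
#' @param table a [weight_table()].
#' @return integer count of records.
#' @export
n_snps <- function(table) nrow(table)

#' Load a PRS weight table from a tab-separated file
#'
#' The file must have a header naming at least `snp_id`, `effect_allele`,
#' `other_allele` and `beta`; columns are matched by name, not position.
#' For a double-weighted model a `pi` column is required and the per-SNP
#' weight becomes `beta * pi`; otherwise `weight = beta` and any `pi`
#' column present is carried along but not applied. Weights are parsed as
#' binary64 with no rounding, and row order is preserved.
#'
#' @param path path to the TSV weight file.
#' @param double_weighted logical; apply the `beta * pi` double weighting.
#' @param model_name label for the model; defaults to the file name.
#' @return A [weight_table()].
#' @export
load_weights <- function(path, double_weighted = FALSE,
                         model_name = sub("\\.[^.]*$", "", basename(path))) {
  df <- read_tsv(path)
  required <- c("snp_id", "effect_allele", "other_allele", "beta")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("weight file '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (double_weighted && !("pi" %in% names(df))) {
    stop("double-weighted model requires a 'pi' column in '", path, "'")
  }
  out <- data.frame(snp_id = as.character(df$snp_id),
                    effect_allele = toupper(as.character(df$effect_allele)),
                    other_allele = toupper(as.character(df$other_allele)),
                    beta = as.numeric(df$beta),
                    stringsAsFactors = FALSE)
  out$pi <- if ("pi" %in% names(df)) as.numeric(df$pi) else NA_real_
  out$weight <- if (double_weighted) out$beta * out$pi else out$beta
  if (double_weighted && anyNA(out$pi)) {
    stop("double-weighted model has missing pi for SNP(s): ",
         paste(utils::head(out$snp_id[is.na(out$pi)], 5L), collapse = ", "))
  }
  validate_weight_table(out)
  new_weight_table(out, model_name)
}

#' Write a weight table to a tab-separated file
#'
#' Numeric columns are written with 17 significant digits so that a
#' write/load round trip reproduces every weight bit-exactly.
#'
#' @param table a [weight_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(table, path) {
  out <- data.frame(snp_id = table$snp_id,
                    effect_allele = table$effect_allele,
                    other_allele = table$other_allele,
                    beta = fmt_double(table$beta),
                    stringsAsFactors = FALSE)
  if (!all(is.na(table$pi))) out$pi <- fmt_double(table$pi)
  write_tsv(out, path)
}

#' Orient a weight table so every weight is risk-increasing
#'
#' For each record with a negative weight the alleles are swapped and the
#' sign of `beta` (hence of `weight`) is flipped, so that the effect allele
#' is always the allele that raises the score. Zero-weight records are left
#' unchanged. Swapping alleles shifts each sample's raw score by the
#' constant `2 * |w|` per flipped SNP, so score differences between samples
#' (and all scaled scores) are unaffected. The operation is idempotent.
#'
#' @param table a [weight_table()].
#' @return A [weight_table()] with all weights non-negative.
#' @export
orient_to_risk_increasing <- function(table) {
  neg <- table$weight < 0
  if (any(neg)) {
    ea <- table$effect_allele[neg]
    table$effect_allele[neg] <- table$other_allele[neg]
    table$other_allele[neg] <- ea
    table$beta[neg] <- -table$beta[neg]
    table$weight[neg] <- -table$weight[neg]
  }
  table
}

#' @export
print.weight_table <- function(x, ...) {
  cat(sprintf("PRS weight table '%s': %d SNPs (%s)\n",
              attr(x, "model_name") %||% "model", nrow(x),
              if (all(is.na(x$pi))) "single-weighted" else "double-weighted"))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
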