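#' Is an allele pair palindromic (strand-ambiguous)?
#'
#' A SNP is palindromic when its two alleles are reverse complements of
#' each other (A/T or C/G), so the same genotype call reads identically on
#' both strands and the effect allele cannot be matched between datasets
#' without external frequency information.
#'
#' @param a1,a2 single bases in `A/C/G/T`, vectorized; `a1 != a2`.
#' @return logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("A", "G")  # FALSE
#' @export
is_palindromic <- function(a1, a2) {
  a1 <- toupper(as.character(a1)); a2 <- toupper(as.character(a2))
  if (!all(a1 %in% BASES) || !all(a2 %in% BASES)) {
    stop("alleles must be single bases in A/C/G/T")
  }
  if (any(a1 == a2)) stop("the two alleles of a SNP must differ")
  unname(COMPLEMENT[a1] == a2)
}

#' Align VCF dosages to the weight table's effect alleles
#'
#' For every genotype column (which counts the VCF ALT allele after
#' [read_genotypes()]), compares the VCF REF/ALT pair with the model's
#' effect/other pair:
#' \itemize{
#'   \item palindromic model SNPs (A/T or C/G) are dropped and logged
#'     `palindromic` when `drop_palindromic = TRUE`;
#'   \item if the effect allele is the VCF ALT (and other = REF), the
#'     dosage already counts the effect allele and is kept;
#'   \item if the effect allele is the VCF REF (and other = ALT), the
#'     dosage is replaced by `2 - dosage` (missing stays missing);
#'   \item any other configuration (disjoint or partially matching
#'     alleles, indel records) is dropped and logged `allele_mismatch`.
#' }
#' No strand flipping is attempted for non-palindromic mismatches: records
#' that do not match as-is are excluded rather than guessed. Missing
#' dosages pass through untouched; their handling belongs to scoring.
#'
#' @param genotypes a `prs_genotypes` object with ALT-counting dosages.
#' @param table the [weight_table()] the columns belong to.
#' @param drop_palindromic logical; drop strand-ambiguous SNPs. The filter
#'   is a flag because published pipelines differ per model.
#' @param log an existing exclusion log to extend (e.g. from
#'   [read_genotypes()]).
#' @return A `prs_harmonized` object: list with `genotypes` (dosages now
#'   counting the effect allele) and `log` (extended exclusion log).
#' @export
harmonize <- function(genotypes, table, drop_palindromic = TRUE,
                      log = exclusion_log()) {
  stopifnot(inherits(genotypes, "prs_genotypes"))
  cols <- colnames(genotypes$dosages)
  idx <- match(cols, table$snp_id)
  if (anyNA(idx)) {
    stop("genotype column(s) absent from the weight table: ",
         paste(utils::head(cols[is.na(idx)], 5L), collapse = ", "))
  }
  ea <- table$effect_allele[idx]
  oa <- table$other_allele[idx]
  ref <- unname(genotypes$ref[cols])
  alt <- unname(genotypes$alt[cols])

  pal <- is_palindromic(ea, oa)
  valid_site <- ref %in% BASES & alt %in% BASES
  keep_as_is <- valid_site & ea == alt & oa == ref
  flip <- valid_site & ea == ref & oa == alt

  status <- rep("allele_mismatch", length(cols))
  status[keep_as_is] <- "keep"
  status[flip] <- "flip"
  if (drop_palindromic) status[pal] <- "palindromic"

  retained <- status %in% c("keep", "flip")
  dos <- genotypes$dosages[, retained, drop = FALSE]
  flip_cols <- which(status[retained] == "flip")
  if (length(flip_cols)) {
    dos[, flip_cols] <- 2L - dos[, flip_cols]
  }

  dropped <- !retained
  new_log <- rbind(log, exclusion_log(cols[dropped], status[dropped]))
  g <- new_prs_genotypes(dos,
                         ref = stats::setNames(oa[retained], cols[retained]),
                         alt = stats::setNames(ea[retained], cols[retained]),
                         populations = genotypes$populations,
                         counting = "effect")
  structure(list(genotypes = g, log = new_log), class = "prs_harmonized")
}

#' @export
print.prs_harmonized <- function(x, ...) {
  cat(sprintf("harmonized genotypes: %d samples x %d SNPs; %d excluded (%s)\n",
              nrow(x$genotypes$dosages), ncol(x$genotypes$dosages),
              nrow(x$log),
              if (nrow(x$log)) paste(sprintf("%s=%d", names(table(x$log$reason)),
                                             table(x$log$reason)),
                                     collapse = ", ") else "none"))
  invisible(x)
}
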