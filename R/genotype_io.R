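#' Extract model-SNP dosages from a multi-sample VCF
#'
#' Reads the GT field of a VCF and returns a samples x SNPs matrix of ALT
#' allele counts for the SNPs of a weight table, matched by ID (or by a
#' user-supplied alias). Matching is by identifier only, never by position,
#' so no liftover is attempted. At this stage dosages count the VCF ALT
#' allele; orientation to the model's effect allele is done by
#' [harmonize()]. SNPs absent from the VCF are logged with reason
#' `not_in_vcf`; multiallelic records (comma-separated ALT) are excluded
#' with reason `multiallelic`. No imputation of absent SNPs is performed.
#'
#' Half-missing or non-diploid GT entries are treated as missing. If
#' several VCF records resolve to the same model SNP, the first is kept
#' and the rest dropped with a warning.
#'
#' @param vcf path to a VCF 4.x file (plain or bgzipped) with a GT field.
#' @param table a [weight_table()] naming the model SNPs.
#' @param alias_map optional path to (or data frame of) a two-column TSV
#'   with header `alias`, `snp_id`, mapping alternative VCF identifiers to
#'   model identifiers.
#' @return A list with elements `genotypes` (a `prs_genotypes` object:
#'   dosage matrix plus per-SNP REF/ALT) and `log` (exclusion data frame
#'   with columns `snp_id`, `reason`).
#' @export
read_genotypes <- function(vcf, table, alias_map = NULL) {
  v <- tryCatch(suppressWarnings(vcfR::read.vcfR(vcf, verbose = FALSE)),
                error = function(e) stop("failed to read VCF '", vcf, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ids <- as.character(fix[, "ID"])
  ref <- as.character(fix[, "REF"])
  alt <- as.character(fix[, "ALT"])

  resolved <- ids
  if (!is.null(alias_map)) {
    am <- if (is.character(alias_map)) read_tsv(alias_map) else alias_map
    if (!all(c("alias", "snp_id") %in% names(am))) {
      stop("alias map must have columns 'alias' and 'snp_id'")
    }
    lut <- stats::setNames(as.character(am$snp_id), as.character(am$alias))
    unknown <- !(resolved %in% table$snp_id) & resolved %in% names(lut)
    resolved[unknown] <- lut[resolved[unknown]]
  }

  in_model <- resolved %in% table$snp_id
  multi <- grepl(",", alt, fixed = TRUE)
  usable <- in_model & !multi
  dup <- usable & duplicated(replace(resolved, !usable, NA_character_), incomparables = NA)
  if (any(dup)) {
    warning("duplicate VCF records for model SNP(s) ",
            paste(unique(resolved[dup]), collapse = ", "),
            "; keeping the first occurrence of each")
    usable <- usable & !dup
  }

  n_var <- length(ids)
  if (sum(usable)) {
    # extract.gt requires unique IDs; we key rows by index, not name
    if (anyDuplicated(ids)) v@fix[, "ID"] <- make.unique(ids)
    gt <- vcfR::extract.gt(v, element = "GT")
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_var)
    dos <- gt_to_dosage(gt[usable, , drop = FALSE])
    rownames(dos) <- resolved[usable]
    samples <- colnames(v@gt)[-1L]
    colnames(dos) <- samples
    dos <- t(dos)
    # weight-table column order
    keep <- table$snp_id[table$snp_id %in% colnames(dos)]
    dos <- dos[, keep, drop = FALSE]
    ref_kept <- stats::setNames(ref[usable], resolved[usable])[keep]
    alt_kept <- stats::setNames(alt[usable], resolved[usable])[keep]
  } else {
    samples <- colnames(v@gt)[-1L]
    dos <- matrix(integer(0), nrow = length(samples), ncol = 0L,
                  dimnames = list(samples, NULL))
    keep <- character(0)
    ref_kept <- alt_kept <- character(0)
  }

  excluded_multi <- unique(resolved[in_model & multi & !(resolved %in% keep)])
  absent <- setdiff(table$snp_id, c(keep, excluded_multi))
  log <- exclusion_log(c(excluded_multi, absent),
                       c(rep("multiallelic", length(excluded_multi)),
                         rep("not_in_vcf", length(absent))))

  g <- new_prs_genotypes(dos, ref = ref_kept, alt = alt_kept,
                         counting = "alt")
  list(genotypes = g, log = log)
}

new_prs_genotypes <- function(dosages, ref = NULL, alt = NULL,
                              populations = NULL, counting = "alt") {
  structure(list(dosages = dosages,
                 sample_ids = rownames(dosages),
                 snp_ids = colnames(dosages),
                 ref = ref, alt = alt,
                 populations = populations,
                 counting = counting),
            class = "prs_genotypes")
}

exclusion_log <- function(snp_id = character(0), reason = character(0)) {
  data.frame(snp_id = as.character(snp_id), reason = as.character(reason),
             stringsAsFactors = FALSE)
}

# GT string -> ALT allele count; anything not a clean diploid call is NA
gt_to_dosage <- function(g) {
  lut <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
           "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  d <- lut[g]
  matrix(unname(d), nrow = nrow(g), ncol = ncol(g), dimnames = dimnames(g))
}

#' Attach population labels to a genotype matrix
#'
#' @param genotypes a `prs_genotypes` object from [read_genotypes()].
#' @param map path to (or data frame of) a two-column TSV with header
#'   `sample_id`, `population` covering every sample; duplicated samples
#'   are allowed only with a consistent label.
#' @return The genotype object with a `populations` vector attached (one
#'   label per sample, in sample order).
#' @export
attach_populations <- function(genotypes, map) {
  stopifnot(inherits(genotypes, "prs_genotypes"))
  pm <- if (is.character(map)) read_tsv(map) else map
  if (!all(c("sample_id", "population") %in% names(pm))) {
    stop("population map must have columns 'sample_id' and 'population'")
  }
  if (!nrow(pm)) stop("population map is empty")
  pm$sample_id <- as.character(pm$sample_id)
  pm$population <- as.character(pm$population)
  conf <- tapply(pm$population, pm$sample_id, function(z) length(unique(z)))
  if (any(conf > 1L)) {
    stop("conflicting population labels for sample(s): ",
         paste(names(conf)[conf > 1L], collapse = ", "))
  }
  pm <- pm[!duplicated(pm$sample_id), ]
  idx <- match(genotypes$sample_ids, pm$sample_id)
  if (anyNA(idx)) {
    stop("population map is missing sample(s): ",
         paste(utils::head(genotypes$sample_ids[is.na(idx)], 5L),
               collapse = ", "))
  }
  genotypes$populations <- stats::setNames(pm$population[idx],
                                           genotypes$sample_ids)
  genotypes
}

#' Write an exclusion log as TSV
#' @param log data frame with columns `snp_id`, `reason`.
#' @param path output path.
#' @export
write_exclusion_log <- function(log, path) write_tsv(log, path)

#' @export
print.prs_genotypes <- function(x, ...) {
  cat(sprintf("genotype matrix: %d samples x %d SNPs (dosages count the %s allele)\n",
              nrow(x$dosages), ncol(x$dosages),
              if (identical(x$counting, "effect")) "effect" else "VCF ALT"))
  if (!is.null(x$populations)) {
    tab <- table(x$populations)
    cat("populations:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
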