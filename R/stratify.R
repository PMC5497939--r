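#' Per-population distribution summary with quintile thresholds
#'
#' For each population, computes the mean with a normal-approximation 95%
#' confidence interval (`mean +/- 1.96 * sd / sqrt(n)`), the min and max,
#' and the 20/40/60/80% quantiles that bound the five risk quintiles.
#' Quantiles use the linear-interpolation empirical estimator
#' (`stats::quantile` type 7): `q(p) = x_(k) + g * (x_(k+1) - x_(k))` with
#' `k = floor(p (n-1)) + 1`.
#'
#' @param scores a `prs_scores` data frame with population labels.
#' @param value which score axis to summarize; scaled (the default)
#'   matches the convention of reporting all populations on the pooled
#'   z-score axis.
#' @return A `prs_quantiles` data frame with one row per population:
#'   `population`, `n`, `mean`, `ci_low`, `ci_high`, `min`, `q20`, `q40`,
#'   `q60`, `q80`, `max`.
#' @export
summarize_population <- function(scores, value = c("scaled", "raw")) {
  value <- match.arg(value)
  x <- scores[[value]]
  if (all(is.na(x))) stop("scores have no '", value, "' values; run scale_scores() first")
  if (anyNA(scores$population)) stop("scores lack population labels")
  groups <- split(x, scores$population)
  small <- names(groups)[lengths(groups) < 5L]
  if (length(small)) {
    stop("population(s) with fewer than 5 samples: ",
         paste(small, collapse = ", "))
  }
  rows <- lapply(names(groups), function(pop) {
    v <- groups[[pop]]
    n <- length(v)
    m <- mean(v)
    half <- 1.96 * stats::sd(v) / sqrt(n)
    q <- stats::quantile(v, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
    data.frame(population = pop, n = n, mean = m,
               ci_low = m - half, ci_high = m + half,
               min = min(v), q20 = q[1], q40 = q[2], q60 = q[3], q80 = q[4],
               max = max(v), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("prs_quantiles", "data.frame"), value = value)
}

quintile_thresholds <- function(qt, population) {
  i <- match(population, qt$population)
  if (is.na(i)) stop("unknown reference population '", population, "'")
  unlist(qt[i, c("q20", "q40", "q60", "q80")], use.names = FALSE)
}

#' Assign every sample to a risk quintile of a reference population
#'
#' Each sample, from any population, is placed into quintile 1-5 using the
#' 20/40/60/80% thresholds of `reference_pop`. A score exactly equal to a
#' threshold falls into the lower quintile, so quintile 5 means strictly
#' above the reference q80. This is how published risk cut-offs are
#' transferred to individuals outside the cohort they were derived in.
#'
#' @param scores a `prs_scores` data frame.
#' @param qt a `prs_quantiles` table from [summarize_population()].
#' @param reference_pop population whose thresholds are applied.
#' @return Data frame: `sample_id`, `population`, `reference_population`,
#'   `quintile`.
#' @export
assign_quintiles <- function(scores, qt, reference_pop) {
  th <- quintile_thresholds(qt, reference_pop)
  x <- scores[[attr(qt, "value") %||% "scaled"]]
  q <- 1L + (x > th[1]) + (x > th[2]) + (x > th[3]) + (x > th[4])
  data.frame(sample_id = scores$sample_id,
             population = scores$population,
             reference_population = reference_pop,
             quintile = as.integer(q),
             stringsAsFactors = FALSE)
}

#' Quintile occupancy of a target population under a reference's cut-offs
#'
#' Assigns the target population's samples to quintiles using the
#' reference population's thresholds and returns the fraction landing in
#' each quintile. For `target_pop == reference_pop` the fractions are
#' uniform fifths up to 1/n; a shifted target piles up in the extreme
#' quintiles — the mechanism by which risk cut-offs derived in one
#' ancestry mis-stratify another.
#'
#' @param scores a `prs_scores` data frame.
#' @param qt a `prs_quantiles` table.
#' @param reference_pop population providing the thresholds.
#' @param target_pop population being stratified.
#' @return Named numeric vector `q1`..`q5`, summing to 1.
#' @export
cross_population_shift <- function(scores, qt, reference_pop, target_pop) {
  if (!target_pop %in% scores$population) {
    stop("unknown target population '", target_pop, "'")
  }
  asg <- assign_quintiles(scores, qt, reference_pop)
  tgt <- asg$quintile[asg$population == target_pop]
  stats::setNames(tabulate(tgt, nbins = 5L) / length(tgt),
                  paste0("q", 1:5))
}

#' Logistic odds ratio of a binary phenotype per scaled-PRS unit
#'
#' Fits `phenotype ~ scaled PRS` by maximum-likelihood logistic regression
#' (intercept plus slope) and reports the odds ratio per scaled-PRS unit
#' (i.e. per pooled standard deviation of the score) with a Wald 95%
#' confidence interval.
#'
#' @param scores a `prs_scores` data frame with `scaled` filled.
#' @param phenotype binary vector (0/1 or logical), one per sample, in
#'   score order; both classes must be present.
#' @return List: `or`, `ci_low`, `ci_high`, `log_or`, `se`, `p_value`, `n`.
#' @export
fit_prs_logistic <- function(scores, phenotype) {
  y <- as.integer(phenotype)
  if (length(y) != nrow(scores)) stop("phenotype length must match scores")
  if (!all(y %in% c(0L, 1L))) stop("phenotype must be binary 0/1")
  if (length(unique(y)) < 2L) {
    stop("both phenotype classes must be present (all cases or all controls)")
  }
  x <- scores$scaled
  if (anyNA(x)) stop("scaled scores required; run scale_scores() first")
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  cf <- summary(fit)$coefficients
  slope <- cf["x", "Estimate"]
  se <- cf["x", "Std. Error"]
  if (!fit$converged || abs(slope) > 15 || se > 100) {
    stop("logistic fit unstable: complete or quasi-complete separation of the phenotype by the score")
  }
  list(or = exp(slope),
       ci_low = exp(slope - 1.96 * se),
       ci_high = exp(slope + 1.96 * se),
       log_or = slope, se = se,
       p_value = cf["x", "Pr(>|z|)"],
       n = length(y))
}
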