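#' Differential-expression decision thresholds
#'
#' Defaults: fold change 1.5, p < 0.05, FDR <= 0.1.
#'
#' @param fold_change minimum fold change (> 1); the log2 cut is
#'   \code{log2(fold_change)} exactly.
#' @param p_max maximum p-value (exclusive).
#' @param fdr_max maximum FDR (inclusive).
#' @return A validated list of class \code{"de_thresholds"}.
#' @export
de_thresholds <- function(fold_change = 1.5, p_max = 0.05, fdr_max = 0.1) {
  if (fold_change <= 1) stop("fold_change must exceed 1")
  if (p_max <= 0 || p_max >= 1) stop("p_max must lie in (0, 1)")
  if (fdr_max <= 0 || fdr_max >= 1) stop("fdr_max must lie in (0, 1)")
  structure(list(fold_change = fold_change, p_max = p_max,
                 fdr_max = fdr_max), class = "de_thresholds")
}

#' TMM (trimmed mean of M-values) normalization factors
#'
#' Computes between-sample scaling factors from pairwise log-ratios against a
#' reference sample: M-values trimmed 30\% two-sided and log-abundances (A)
#' trimmed 5\% two-sided, with inverse-asymptotic-variance precision
#' weights; factors are rescaled to geometric mean 1.  Effective library
#' size = column sum x factor.
#'
#' @param cm a \code{\link{count_matrix}} (or plain integer matrix).
#' @param reference_sample optional sample id; when \code{NULL}, the sample
#'   whose 75th count percentile (relative to library size) is closest to the
#'   mean is used.
#' @return Named numeric vector of factors, one per sample, with attribute
#'   \code{"effective_lib_size"}.
#' @export
tmm_size_factors <- function(cm, reference_sample = NULL) {
  y <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  lib <- colSums(y)
  zero <- lib == 0
  if (any(zero))
    stop("all-zero sample(s): ", paste(colnames(y)[zero], collapse = ", "))
  f75 <- apply(y, 2L, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- if (is.null(reference_sample)) {
    which.min(abs(f75 - mean(f75)))
  } else {
    match(reference_sample, colnames(y))
  }
  if (is.na(ref)) stop("unknown reference sample: ", reference_sample)
  f <- vapply(seq_len(ncol(y)), function(j)
    tmm_pair(y[, j], y[, ref], lib[j], lib[ref]), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(y)
  attr(f, "effective_lib_size") <- lib * f
  f
}

# single-pair trimmed-mean factor (obs vs ref), on the log2 scale
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, sum_trim = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1
  hiS <- n + 1 - loS
  keep2 <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep2] / v[keep2], na.rm = TRUE) /
    sum(1 / v[keep2], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2 ^ f
}

#' Counts normalized to a common effective library size
#'
#' @inheritParams tmm_size_factors
#' @param size_factors optional precomputed \code{\link{tmm_size_factors}}.
#' @return Real-valued matrix: counts rescaled so every column has the same
#'   effective library size (the geometric mean of the originals).
#' @export
normalized_counts <- function(cm, size_factors = NULL) {
  y <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(size_factors)) size_factors <- tmm_size_factors(cm)
  N <- colSums(y) * as.numeric(size_factors)
  sweep(y, 2L, exp(mean(log(N))) / N, `*`)
}

#' Method-of-moments common negative-binomial dispersion
#'
#' Pools within-group means and variances of normalized counts across all
#' features: under NB, variance = mean + phi * mean^2, so
#' \code{phi = sum(var - mean) / sum(mean^2)}, floored at 0.
#'
#' @inheritParams normalized_counts
#' @return Scalar dispersion estimate \code{phi >= 0}.
#' @export
estimate_common_dispersion <- function(cm, size_factors = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  z <- normalized_counts(cm, size_factors)
  groups <- split(seq_len(ncol(z)), cm$conditions)
  groups <- groups[lengths(groups) >= 2L]
  if (length(groups) == 0L)
    stop("dispersion unidentifiable: no condition has >= 2 replicates")
  num <- 0; den <- 0
  for (g in groups) {
    m <- rowMeans(z[, g, drop = FALSE])
    v <- apply(z[, g, drop = FALSE], 1L, stats::var)
    num <- num + sum(v - m)
    den <- den + sum(m ^ 2)
  }
  max(0, num / den)
}

#' Exact negative-binomial test for a two-group comparison
#'
#' Counts are rescaled to a common effective library size (pseudo-counts) and
#' summed within each group; conditional on the two group totals, the
#' two-sided p-value sums the probabilities of all splits no more likely
#' than the observed one under NB with the given dispersion (minimum-
#' likelihood two-sided rule, ties included).  With \code{phi = 0} the NB
#' reduces to Poisson and the conditional law is exactly binomial.
#'
#' @inheritParams normalized_counts
#' @param phi common dispersion (see
#'   \code{\link{estimate_common_dispersion}}).
#' @param conditions optional length-2 character vector selecting and
#'   ordering the two conditions as (reference, treatment); defaults to
#'   order of appearance.
#' @return \code{data.frame}: \code{feature_id}, \code{log2fc} (treatment vs
#'   reference, 0.5 pseudo-count), \code{p_value}, and the per-group
#'   normalized means.  All-zero features get \code{p = 1, log2fc = 0}.
#' @export
nb_exact_test <- function(cm, phi, size_factors = NULL, conditions = NULL) {
  stopifnot(inherits(cm, "count_matrix"), phi >= 0)
  if (is.null(conditions)) conditions <- unique(cm$conditions)
  if (length(conditions) != 2L)
    stop("nb_exact_test requires exactly two conditions")
  if (is.null(size_factors)) size_factors <- tmm_size_factors(cm)
  z <- normalized_counts(cm, size_factors)
  ga <- which(cm$conditions == conditions[1L])  # reference
  gb <- which(cm$conditions == conditions[2L])  # treatment
  if (length(ga) == 0L || length(gb) == 0L)
    stop("condition without samples")
  na <- length(ga); nb <- length(gb)
  mean_a <- rowMeans(z[, ga, drop = FALSE])
  mean_b <- rowMeans(z[, gb, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))
  sa <- round(rowSums(z[, ga, drop = FALSE]))
  sb <- round(rowSums(z[, gb, drop = FALSE]))
  p <- vapply(seq_len(nrow(z)), function(i)
    exact_split_p(sa[i], sb[i], na, nb, phi), numeric(1))
  allzero <- sa + sb == 0
  log2fc[allzero] <- 0
  data.frame(feature_id = rownames(z), log2fc = log2fc, p_value = p,
             mean_reference = mean_a, mean_treatment = mean_b,
             row.names = NULL, stringsAsFactors = FALSE)
}

# two-sided conditional p for an observed (sa, sb) split of s = sa + sb
# between groups of na and nb samples sharing per-sample mean s / (na + nb)
exact_split_p <- function(sa, sb, na, nb, phi) {
  s <- sa + sb
  if (s == 0) return(1)
  mu <- s / (na + nb)
  k <- 0:s
  logp <- if (phi > 0) {
    stats::dnbinom(k, size = na / phi, mu = na * mu, log = TRUE) +
      stats::dnbinom(s - k, size = nb / phi, mu = nb * mu, log = TRUE)
  } else {
    stats::dpois(k, na * mu, log = TRUE) +
      stats::dpois(s - k, nb * mu, log = TRUE)
  }
  pr <- exp(logp - max(logp))
  obs <- pr[sa + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-10)]) / sum(pr))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjustment via \code{stats::p.adjust}.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return FDR (adjusted p) values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Label features up / down / unchanged
#'
#' A feature is \code{up} iff \code{log2fc >= log2(fold_change)},
#' \code{p_value < p_max} and \code{fdr <= fdr_max}; \code{down} with the
#' negated log2 cut; otherwise \code{unchanged}.
#'
#' @param results \code{data.frame} with columns \code{log2fc},
#'   \code{p_value} and \code{fdr}.
#' @param thresholds a \code{\link{de_thresholds}}.
#' @return \code{results} with a \code{label} column added.
#' @export
classify_de <- function(results, thresholds = de_thresholds()) {
  lcut <- log2(thresholds$fold_change)
  sig <- results$p_value < thresholds$p_max & results$fdr <= thresholds$fdr_max
  label <- rep("unchanged", nrow(results))
  label[sig & results$log2fc >= lcut] <- "up"
  label[sig & results$log2fc <= -lcut] <- "down"
  results$label <- label
  results
}

#' Full two-group differential-expression analysis
#'
#' TMM normalization, common-dispersion estimation, exact NB test, BH
#' adjustment and threshold labeling in one call.
#'
#' @inheritParams nb_exact_test
#' @param thresholds a \code{\link{de_thresholds}}.
#' @return A \code{data.frame} of class \code{"de_result"} with columns
#'   \code{feature_id}, \code{log2fc}, \code{p_value}, \code{fdr},
#'   group means and \code{label}; dispersion and size factors are attached
#'   as attributes.
#' @export
de_analysis <- function(cm, thresholds = de_thresholds(),
                        conditions = NULL) {
  sf <- tmm_size_factors(cm)
  phi <- estimate_common_dispersion(cm, sf)
  res <- nb_exact_test(cm, phi, sf, conditions)
  res$fdr <- bh_adjust(res$p_value)
  res <- classify_de(res, thresholds)
  z <- normalized_counts(cm, sf)
  colnames(z) <- paste0("norm_", colnames(z))
  res <- cbind(res, as.data.frame(z[match(res$feature_id, rownames(z)), ,
                                    drop = FALSE], row.names = NULL))
  attr(res, "dispersion") <- phi
  attr(res, "size_factors") <- sf
  class(res) <- c("de_result", "data.frame")
  res
}

#' Unpaired two-tailed Student's t-test with significance stars
#'
#' Pooled-variance t-test on (normalized) per-sample values between two
#' groups.  Stars follow the usual convention: 1 for p < 0.05, 2 for
#' p < 0.01, 3 for p < 0.001.
#'
#' @param values numeric vector, one entry per sample.
#' @param groups vector of group labels (exactly two distinct values, each
#'   with >= 2 samples).
#' @return List with \code{p_value} and \code{stars}.
#' @export
group_t_test <- function(values, groups) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("group_t_test requires exactly two groups")
  a <- values[groups == lv[1L]]
  b <- values[groups == lv[2L]]
  if (length(a) < 2L || length(b) < 2L)
    stop("need >= 2 replicates per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    p <- stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  list(p_value = p, stars = significance_stars(p))
}

#' @rdname group_t_test
#' @param p a p-value.
#' @export
significance_stars <- function(p) {
  if (p < 0.001) 3L else if (p < 0.01) 2L else if (p < 0.05) 1L else 0L
}

#' Pearson correlation of fold changes across platforms
#'
#' Correlates two named log2 fold-change vectors over the intersection of
#' their feature ids, dropping pairs with missing values.
#'
#' @param log2fc_a,log2fc_b named numeric vectors.
#' @param shared_ids optional character vector restricting the comparison.
#' @return List with \code{r} (Pearson product-moment correlation) and
#'   \code{n} (pairs used).  Fewer than 3 finite pairs is an error.
#' @export
platform_correlation <- function(log2fc_a, log2fc_b, shared_ids = NULL) {
  ids <- intersect(names(log2fc_a), names(log2fc_b))
  if (!is.null(shared_ids)) ids <- intersect(ids, shared_ids)
  a <- log2fc_a[ids]; b <- log2fc_b[ids]
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3L)
    stop("platform_correlation needs >= 3 shared finite pairs, got ", sum(ok))
  list(r = stats::cor(a[ok], b[ok]), n = sum(ok))
}
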