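test_that("TMM factors match a literal trimmed-mean re-computation", {
  set.seed(31)
  y <- matrix(rnbinom(3000 * 6, size = 8, mu = rep(exp(runif(3000, 2, 7)), 6)),
              ncol = 6, dimnames = list(paste0("g", 1:3000), paste0("s", 1:6)))
  f <- tmm_size_factors(y, reference_sample = "s1")
  expect_equal(as.vector(f), oracle_tmm(y, 1L), tolerance = 1e-10)
})

test_that("TMM agrees with the edgeR implementation", {
  set.seed(33)
  y <- matrix(rnbinom(2000 * 8, size = 10,
                      mu = rep(exp(runif(2000, 2, 7)), 8) *
                        rep(exp(runif(8, -0.5, 0.5)), each = 2000)),
              ncol = 8, dimnames = list(paste0("g", 1:2000), paste0("s", 1:8)))
  f_edger <- edgeR::calcNormFactors(edgeR::DGEList(counts = y),
                                    method = "TMM")$samples$norm.factors
  expect_equal(as.vector(tmm_size_factors(y)), f_edger, tolerance = 1e-10)
})

test_that("TMM is 1 for identical libraries and equivariant under scaling", {
  y <- matrix(rep(c(5L, 20L, 100L, 7L), 4), ncol = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  expect_equal(as.vector(tmm_size_factors(y)), rep(1, 4))

  set.seed(35)
  y2 <- matrix(rnbinom(2000 * 4, size = 10,
                       mu = rep(exp(runif(2000, 2, 7)), 4)),
               ncol = 4, dimnames = list(paste0("g", 1:2000),
                                         paste0("s", 1:4)))
  y3 <- y2; y3[, 2] <- y3[, 2] * 4L
  f2 <- tmm_size_factors(y2); f3 <- tmm_size_factors(y3)
  n2 <- attr(f2, "effective_lib_size"); n3 <- attr(f3, "effective_lib_size")
  # effective library size scales (almost exactly) with the rescaling; the
  # residual comes from the depth-dependent precision weights in the
  # trimmed mean, which edgeR's TMM shares
  expect_equal(unname(n3[2] / n2[2]), 4, tolerance = 0.01)
  expect_equal(sweep(y3, 2, n3, `/`), sweep(y2, 2, n2, `/`),
               tolerance = 0.01)

  y4 <- y2; y4[, 3] <- 0L
  expect_error(tmm_size_factors(y4), "s3")
})

test_that("common dispersion is recovered by method of moments", {
  cm_pois <- nb_counts(2000L, phi = 0, lambda = exp(runif(2000, 4, 6)),
                       seed = 41L)
  expect_lte(estimate_common_dispersion(cm_pois), 0.02)

  cm_nb <- nb_counts(2000L, phi = 0.1, lambda = exp(runif(2000, 4, 6)),
                     seed = 43L)
  phi_hat <- estimate_common_dispersion(cm_nb)
  expect_gte(phi_hat, 0.07)
  expect_lte(phi_hat, 0.13)

  # identical replicate columns: zero within-group variance, phi = 0
  y <- matrix(rep(c(10L, 50L, 3L), 4), ncol = 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  cm0 <- count_matrix(y, rep(c("a", "b"), each = 2))
  expect_equal(estimate_common_dispersion(cm0, rep(1, 4)), 0)

  cm1 <- count_matrix(y[, 1:2], c("a", "b"))
  expect_error(estimate_common_dispersion(cm1), "unidentifiable")
})

test_that("exact NB test handles degenerate and symmetric inputs", {
  y <- matrix(c(0L, 3L, 0L, 12L, 0L, 9L, 0L, 6L), nrow = 2,
              dimnames = list(c("zero", "g"), paste0("s", 1:4)))
  cm <- count_matrix(y, rep(c("a", "b"), each = 2))
  res <- nb_exact_test(cm, phi = 0.1, size_factors = rep(1, 4))
  expect_equal(res$p_value[res$feature_id == "zero"], 1)
  expect_equal(res$log2fc[res$feature_id == "zero"], 0)

  # swapping the groups negates log2fc and keeps p
  cm_sw <- count_matrix(y[, c(3, 4, 1, 2)], rep(c("a", "b"), each = 2))
  res_sw <- nb_exact_test(cm_sw, phi = 0.1, size_factors = rep(1, 4))
  expect_equal(res_sw$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(res_sw$log2fc, -res$log2fc, tolerance = 1e-12)
})

test_that("phi = 0 equal-library p-values equal the binomial tail sum", {
  # conditional law of the group split for Poisson counts with equal
  # libraries is Binomial(total, 1/2); minimum-likelihood two-sided sum
  p_binom <- function(a, b) {
    s <- a + b
    pr <- dbinom(0:s, s, 0.5)
    sum(pr[pr <= pr[a + 1] * (1 + 1e-10)])
  }
  for (s in c(1L, 2L, 7L, 15L, 50L)) {
    for (a in 0:s) {
      # a balancing second feature keeps the two library sizes equal (and
      # nonzero) so no rescaling happens and the conditional law is exact
      y <- matrix(c(a, 10L + s - a, s - a, 10L + a), nrow = 2,
                  dimnames = list(c("g", "balance"), c("s1", "s2")))
      cm <- count_matrix(y, c("x", "y"))
      res <- nb_exact_test(cm, phi = 0, size_factors = rep(1, 2))
      expect_equal(res$p_value[1L], p_binom(a, s - a), tolerance = 1e-12)
    }
  }
  # the 3-vs-12 case: Binomial(15, 1/2)
  y <- matrix(c(3L, 22L, 12L, 13L), nrow = 2,
              dimnames = list(c("g", "balance"), c("s1", "s2")))
  cm <- count_matrix(y, c("x", "y"))
  expect_equal(nb_exact_test(cm, 0, size_factors = rep(1, 2))$p_value[1L],
               p_binom(3, 12), tolerance = 1e-12)
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
})

test_that("DE labels apply the fold-change, p and FDR cuts jointly", {
  res <- data.frame(
    feature_id = paste0("g", 1:4),
    log2fc = c(1.0, 0.5, -2, -1),
    p_value = c(0.001, 0.001, 0.04, 0.06),
    fdr = c(0.01, 0.01, 0.2, 0.01))
  lab <- classify_de(res, de_thresholds())$label
  expect_equal(lab, c("up", "unchanged", "unchanged", "unchanged"))

  # label antisymmetry under swapping condition roles
  res2 <- res; res2$log2fc <- -res$log2fc
  lab2 <- classify_de(res2, de_thresholds())$label
  expect_equal(lab2, ifelse(lab == "up", "down", ifelse(lab == "down", "up",
                                                        "unchanged")))
})

test_that("group t-test matches the pooled-variance computation", {
  a <- c(10, 10, 10, 10); b <- c(20, 20, 20, 21)
  # textbook pooled-variance t
  sp2 <- (3 * var(a) + 3 * var(b)) / 6
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(tstat), df = 6)
  res <- group_t_test(c(a, b), rep(c("wt", "mut"), each = 4))
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)

  same <- group_t_test(rep(5, 8), rep(c("wt", "mut"), each = 4))
  expect_equal(same$p_value, 1)
  expect_equal(same$stars, 0L)

  expect_equal(significance_stars(0.0005), 3L)
  expect_equal(significance_stars(0.005), 2L)
  expect_equal(significance_stars(0.03), 1L)
  expect_equal(significance_stars(0.2), 0L)
})

test_that("platform correlation is Pearson r over shared ids", {
  a <- c(g1 = 1, g2 = 2, g3 = 3)
  expect_equal(platform_correlation(a, a)$r, 1)
  expect_equal(platform_correlation(a, -a)$r, -1)
  b <- c(g1 = 2, g2 = 4, g3 = 7)
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(platform_correlation(a, b)$r, hand, tolerance = 1e-12)
  # missing values are dropped and the pair count reported
  b2 <- c(b, g4 = NA_real_)
  a2 <- c(a, g4 = 1)
  expect_equal(platform_correlation(a2, b2)$n, 3L)
  expect_error(platform_correlation(a[1:2], b[1:2]), "3")
})
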