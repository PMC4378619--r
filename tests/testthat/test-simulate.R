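test_that("locus layouts place downstream genes as designed", {
  cfg <- simulation_config(n_loci = 12L, seed = 5L)
  sim <- simulate_locus_set(cfg)
  loci <- sim$truth$loci
  conv <- loci[loci$layout == "tail_to_tail", ]
  # convergent gene TSS (its 5'-most base in its own orientation) lies
  # inside the parent's extension span
  expect_true(all(conv$gene_tss >= pmin(conv$ext_start, conv$ext_end)))
  expect_true(all(conv$gene_tss < pmax(conv$ext_start, conv$ext_end)))
  # convergent genes sit on the opposite strand, tandem genes on the same
  expect_true(all(conv$gene_strand != conv$strand))
  tand <- loci[loci$layout == "tail_to_head", ]
  expect_true(all(tand$gene_strand == tand$strand))
  iso <- loci[loci$layout == "isolated", ]
  expect_true(all(is.na(iso$gene_id)))

  # determinism: same config, same output
  sim2 <- simulate_locus_set(cfg)
  expect_identical(sim, sim2)

  empty <- simulate_locus_set(simulation_config(n_loci = 0L))
  expect_equal(nrow(empty$features), 0L)
  expect_error(simulate_locus_set(simulation_config(contig_length = 1000L,
                                                    n_loci = 5L)),
               "too short")
})

test_that("noise-free coverage matches its closed-form expectation", {
  base <- list(n_loci = 3L, layouts = "isolated", noise = FALSE,
               lambda = 200, coverage_scale = 0.25, seed = 2L)
  # rho = 0: nothing outside mature spans
  cfg0 <- do.call(simulation_config, c(base, list(
    readthrough_fraction = c(wildtype = 0, mutant = 0))))
  sim0 <- simulate_locus_set(cfg0)
  cov0 <- simulate_coverage(sim0, "mutant")
  mask <- numeric(cfg0$contig_length)
  for (i in seq_len(nrow(sim0$features)))
    mask[(sim0$features$start[i] + 1L):sim0$features$end[i]] <- 1
  expect_true(all(cov0[["+"]]$values[mask == 0] == 0))
  expect_true(all(cov0[["-"]]$values[mask == 0] == 0))

  # rho = 1: extension depth equals mature depth exactly
  cfg1 <- do.call(simulation_config, c(base, list(
    readthrough_fraction = c(wildtype = 0, mutant = 1))))
  sim1 <- simulate_locus_set(cfg1)
  cov1 <- simulate_coverage(sim1, "mutant")
  l1 <- sim1$truth$loci[1L, ]
  trk <- cov1[[l1$strand]]$values
  mat <- trk[(l1$parent_start + 1L):l1$parent_end]
  ext <- trk[(min(l1$ext_start, l1$ext_end) + 1L):max(l1$ext_start,
                                                      l1$ext_end)]
  expect_equal(unique(mat), unique(ext))

  # rho = 0.2 at 50x mature depth: extension depth 10 (= 50 * 0.2)
  cfg2 <- do.call(simulation_config, c(base, list(
    readthrough_fraction = c(wildtype = 0, mutant = 0.2))))
  sim2 <- simulate_locus_set(cfg2)
  cov2 <- simulate_coverage(sim2, "mutant")
  l2 <- sim2$truth$loci[1L, ]
  trk2 <- cov2[[l2$strand]]$values
  expect_equal(unique(trk2[(l2$parent_start + 1L):l2$parent_end]), 50)
  expect_equal(unique(trk2[(min(l2$ext_start, l2$ext_end) + 1L):
                             max(l2$ext_start, l2$ext_end)]), 10)
})

test_that("noise-free coverage mass equals lambda-weighted span lengths", {
  cfg <- simulation_config(
    n_loci = 4L, layouts = "isolated", noise = FALSE, lambda = 100,
    coverage_scale = 0.5, processing_intermediate_fraction = 0.3,
    pre_rna_length = 40L,
    readthrough_fraction = c(wildtype = 0.1, mutant = 0.6), seed = 9L)
  sim <- simulate_locus_set(cfg)
  for (cond in c("wildtype", "mutant")) {
    cov <- simulate_coverage(sim, cond)
    total <- sum(cov[["+"]]$values) + sum(cov[["-"]]$values)
    rho <- cfg$readthrough_fraction[[cond]]
    expected <- cfg$n_loci * cfg$coverage_scale * 100 *
      (cfg$feature_length + rho * cfg$extension_length + 0.3 * 40)
    expect_equal(total, expected)
  }
})

test_that("count simulation is seeded, NB-dispersed, and truth-consistent", {
  cfg <- simulation_config(n_loci = 1000L, layouts = "isolated",
                           contig_length = 3000000L, nb_dispersion = 0.1,
                           seed = 13L)
  sim <- simulate_locus_set(cfg)
  cm <- simulate_counts(sim)
  cm2 <- simulate_counts(sim)
  expect_identical(cm$counts, cm2$counts)
  # empirical dispersion of the generated counts recovers phi
  phi_hat <- estimate_common_dispersion(cm)
  expect_gt(phi_hat, 0.07)
  expect_lt(phi_hat, 0.13)
  # no planted effects: true log2 fold changes are all zero
  expect_true(all(attr(cm, "true_log2fc") == 0))
})

test_that("Poisson branch of the count model has the right mean", {
  cfg <- simulation_config(n_loci = 2500L, layouts = "isolated",
                           contig_length = 7000000L, nb_dispersion = 0,
                           lambda = 1000, replicates_per_condition = 2L,
                           seed = 3L)
  sim <- simulate_locus_set(cfg)
  cm <- simulate_counts(sim)
  s <- attr(cm, "size_factors")
  # divide out the library size factor: 10^4 draws of mean 1000
  z <- sweep(cm$counts, 2L, s, `/`)
  expect_gt(mean(z), 980)
  expect_lt(mean(z), 1020)
})

test_that("interference repression is encoded in the ground truth", {
  cfg <- simulation_config(n_loci = 6L, layouts = "tail_to_tail",
                           interference_coefficient = 0.5, seed = 4L)
  sim <- simulate_locus_set(cfg)
  genes <- sim$truth$loci$gene_id
  expect_equal(unname(sim$truth$log2fc[genes]), rep(log2(0.5), 6L),
               tolerance = 1e-12)
  expect_equal(unname(sim$truth$log2fc[sim$truth$loci$parent_id]),
               rep(0, 6L))
  expect_equal(nrow(sim$truth$interference_pairs), 6L)
})

test_that("occupancy tracks shift their termination peak by Delta", {
  base <- list(n_loci = 2L, layouts = "isolated", noise = FALSE,
               readthrough_fraction = c(wildtype = 0.2, mutant = 0.2),
               seed = 6L)
  cfg0 <- do.call(simulation_config, c(base, list(occupancy_shift = 0L)))
  sim0 <- simulate_locus_set(cfg0)
  wt <- simulate_occupancy(sim0, "wildtype")
  mut <- simulate_occupancy(sim0, "mutant")
  expect_identical(wt, mut)

  cfg1 <- do.call(simulation_config, c(base, list(occupancy_shift = 150L)))
  sim1 <- simulate_locus_set(cfg1)
  wt1 <- simulate_occupancy(sim1, "wildtype")
  mut1 <- simulate_occupancy(sim1, "mutant")
  l <- sim1$truth$loci[1L, ]
  f3 <- if (l$strand == "+") l$parent_end else l$parent_start
  dir <- if (l$strand == "+") 1L else -1L
  win <- sort(c(f3 + dir * 10L, f3 + dir * 400L))
  peak_at <- function(cov) {
    v <- cov[[l$strand]]$values
    which.max(v[(win[1L] + 1L):win[2L]]) + win[1L] - 1L
  }
  expect_equal(peak_at(mut1) - peak_at(wt1), dir * 150L)
})
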