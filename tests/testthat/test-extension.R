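test_that("orientation classification matches the figure geometries", {
  f <- one_feature(100, 200, "+")
  expect_equal(classify_orientation(f, one_feature(300, 500, "-", "n")),
               "tail_to_tail")
  expect_equal(classify_orientation(f, one_feature(400, 700, "+", "n")),
               "tail_to_head")
  expect_equal(classify_orientation(f, one_feature(150, 400, "-", "n")),
               "overlapping")
  expect_error(classify_orientation(f, one_feature(0, 50, "+", "n")),
               "downstream")
})

test_that("orientation agrees with brute-force enumeration on a toy contig", {
  n_checked <- 0L
  for (fs in 0:8) for (fe in (fs + 1):9) {
    for (ns in 0:8) for (ne in (ns + 1):9) {
      for (fstr in c("+", "-")) for (nstr in c("+", "-")) {
        f3 <- if (fstr == "+") fe else fs
        overlapping <- fs < ne && ns < fe
        downstream <- if (fstr == "+") ne > f3 else ns < f3
        if (!overlapping && !downstream) next
        got <- classify_orientation(
          list(start = fs, end = fe, strand = fstr),
          list(start = ns, end = ne, strand = nstr))
        expect_identical(got, oracle_orientation(fs, fe, fstr, ns, ne, nstr))
        n_checked <- n_checked + 1L
      }
    }
  }
  expect_gt(n_checked, 2000L)
})

test_that("extension calls follow the orientation-aware stopping rules", {
  params <- extension_params(min_coverage = 5, max_gap = 10L,
                             min_et_length = 25L)
  f <- one_feature(100, 200, "+", "snR")
  cov <- block_coverage(1000L, list(c(100L, 450L, 50)))

  # tail-to-tail neighbor: no positional cap, call runs to the coverage end
  nb_tt <- rbind(f, one_feature(500, 800, "-", "gene", "ORF_T"))
  cl <- call_extension(f, cov, nb_tt, params)
  expect_equal(c(cl$et_start, cl$et_end), c(200L, 450L))
  expect_equal(cl$stop_reason, "coverage_gap")

  # tail-to-head neighbor with TSS at 400 caps the call there
  nb_th <- rbind(f, one_feature(400, 800, "+", "gene", "ORF_T"))
  cl2 <- call_extension(f, cov, nb_th, params)
  expect_equal(c(cl2$et_start, cl2$et_end), c(200L, 400L))
  expect_equal(cl2$stop_reason, "downstream_tss")

  # a sub-threshold run of 8 <= max_gap is bridged
  gap_cov <- block_coverage(1000L, list(c(100L, 300L, 50), c(308L, 450L, 50)))
  cl3 <- call_extension(f, gap_cov, nb_tt, params)
  expect_equal(c(cl3$et_start, cl3$et_end), c(200L, 450L))

  # zero coverage downstream: nothing called
  zero_cov <- block_coverage(1000L, list(c(100L, 200L, 50)))
  cl4 <- call_extension(f, zero_cov, nb_tt, params)
  expect_equal(cl4$stop_reason, "none_called")
  expect_equal(cl4$length, 0L)

  # intron-hosted parent: stops at the host exon boundary
  cl5 <- call_extension(f, cov, params = params, exon_boundary = 350L)
  expect_equal(c(cl5$et_start, cl5$et_end), c(200L, 350L))
  expect_equal(cl5$stop_reason, "exon_boundary")

  # 3' end at the contig edge: warning, none called
  edge <- one_feature(900, 1000, "+", "edge")
  expect_warning(cl6 <- call_extension(edge, cov, params = params),
                 "contig edge")
  expect_equal(cl6$stop_reason, "none_called")
})

test_that("sub-threshold runs longer than max_gap end the call", {
  params <- extension_params(min_coverage = 5, max_gap = 10L,
                             min_et_length = 0L)
  f <- one_feature(100, 200, "+", "snR")
  # brute-force scan oracle over random gap layouts
  set.seed(21)
  for (rep in 1:20) {
    v <- numeric(1000L)
    v[101:200] <- 50
    on <- 200L
    while (on < 700L) {
      gap <- sample.int(30L, 1L)
      run <- sample.int(80L, 1L)
      if (on + gap + run > 900L) break
      v[(on + gap + 1L):(on + gap + run)] <- 50
      on <- on + gap + run
    }
    cov <- stranded_coverage("chrI", "+", v)
    # oracle: walk base by base tracking the sub-threshold run length
    pos <- 200L; last_good <- 200L; gap_run <- 0L
    while (pos < 1000L) {
      if (v[pos + 1L] >= 5) { last_good <- pos + 1L; gap_run <- 0L }
      else { gap_run <- gap_run + 1L; if (gap_run > 10L) break }
      pos <- pos + 1L
    }
    cl <- call_extension(f, cov, params = params)
    expect_equal(cl$et_end, last_good)
  }
})

test_that("percent extension is the area ratio and is scale-invariant", {
  # parent length 100 at depth 1000, ET length 50 at depth 10
  cov <- block_coverage(400L, list(c(100L, 200L, 1000), c(200L, 250L, 10)))
  pct <- percent_extension(cov, c(100L, 200L), c(200L, 250L))
  expect_equal(pct, 100 * 500 / 100500, tolerance = 1e-12)

  expect_equal(percent_extension(cov, c(100L, 200L), c(250L, 250L)), 0)

  eq <- block_coverage(400L, list(c(100L, 300L, 7)))
  expect_equal(percent_extension(eq, c(100L, 200L), c(200L, 300L)), 50)

  scaled <- stranded_coverage("chrI", "+", cov$values * 17.3)
  expect_equal(percent_extension(scaled, c(100L, 200L), c(200L, 250L)), pct,
               tolerance = 1e-12)

  none <- block_coverage(400L, list(c(0L, 50L, 5)))
  expect_error(percent_extension(none, c(100L, 200L), c(200L, 250L)),
               "zero coverage")
})

test_that("calls recover the true boundary on noise-free coverage", {
  cfg <- simulation_config(n_loci = 9L, noise = FALSE, seed = 17L)
  sim <- simulate_locus_set(cfg)
  cov <- simulate_coverage(sim, "mutant")
  calls <- call_extensions(sim$features, cov)
  et <- sim$truth$et_true
  et <- et[et$condition == "mutant", ]
  for (i in seq_len(nrow(calls))) {
    tr <- et[et$parent_id == calls$parent[i], ]
    expect_equal(calls$et_start[i], tr$call_start)
    expect_equal(calls$et_end[i], tr$call_end)
  }
})

test_that("mirrored genomes give mirrored calls", {
  cfg <- simulation_config(n_loci = 6L, noise = FALSE, seed = 23L)
  sim <- simulate_locus_set(cfg)
  cov <- simulate_coverage(sim, "mutant")
  calls <- call_extensions(sim$features, cov)

  L <- cfg$contig_length
  mirrored <- sim$features
  mirrored$start <- L - sim$features$end
  mirrored$end <- L - sim$features$start
  mirrored$strand <- ifelse(sim$features$strand == "+", "-", "+")
  mcov <- list("+" = stranded_coverage("chrS", "+", rev(cov[["-"]]$values)),
               "-" = stranded_coverage("chrS", "-", rev(cov[["+"]]$values)))
  mcalls <- call_extensions(mirrored, mcov)
  m <- match(calls$parent, mcalls$parent)
  expect_equal(mcalls$et_start[m], L - calls$et_end)
  expect_equal(mcalls$et_end[m], L - calls$et_start)
  expect_equal(mcalls$stop_reason[m], calls$stop_reason)
  expect_equal(mcalls$percent_et[m], calls$percent_et)
})

test_that("reference comparison reports length deltas and overlap", {
  # geometry mirroring a 1396 nt read-through call against a 3363 nt
  # reference annotation over the same locus
  cov <- block_coverage(5000L, list(c(1000L, 2396L, 40)))
  calls <- data.frame(parent = "snR", contig = "chrI", strand = "+",
                      parent_start = 1000L, parent_end = 1200L,
                      et_start = 1200L, et_end = 2396L,
                      stop_reason = "coverage_gap", length = 1196L,
                      percent_et = 50, orientation = "tail_to_tail",
                      stringsAsFactors = FALSE)
  ref <- feature_table("chrI", 1000L, 4363L, "+", "NUT0426", "NUT")
  cmp <- compare_to_reference(calls, ref)
  expect_equal(cmp$call_length, 1396L)
  expect_equal(cmp$reference_length, 3363L)
  expect_equal(cmp$length_delta, 1967L)

  same <- feature_table("chrI", 1000L, 2396L, "+", "NUTx", "NUT")
  cmp2 <- compare_to_reference(calls, same)
  expect_equal(cmp2$length_delta, 0L)
  expect_equal(cmp2$jaccard, 1)

  far <- feature_table("chrI", 4500L, 4800L, "+", "NUTy", "NUT")
  expect_equal(nrow(compare_to_reference(calls, far)), 0L)
})
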