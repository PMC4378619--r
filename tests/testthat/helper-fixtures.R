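# shared fixture builders; everything is generated in code at test time

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a random valid BED6 feature set in canonical form
random_bed_lines <- function(n, contig = "chrI", max_pos = 10000L) {
  start <- sort(sample.int(max_pos - 10L, n))
  len <- sample.int(200L, n)
  sprintf("%s\t%d\t%d\tfeat%03d\t%d\t%s", contig, start, start + len,
          seq_len(n), sample.int(1000L, n), sample(c("+", "-"), n, TRUE))
}

# rectangular coverage: list of c(start, end, value) blocks on one contig
block_coverage <- function(contig_len, blocks, contig = "chrI",
                           strand = "+") {
  v <- numeric(contig_len)
  for (b in blocks) v[(b[1L] + 1L):b[2L]] <- b[3L]
  stranded_coverage(contig, strand, v)
}

one_feature <- function(start, end, strand = "+", id = "f1",
                        class = "snRNA", contig = "chrI") {
  feature_table(contig, start, end, strand, id, class)
}

# NB count matrix with optional per-feature fold changes in group 2
nb_counts <- function(n_features, phi, lambda, n_per_group = 4L,
                      log2fc = 0, size_factors = NULL, seed = 1L) {
  set.seed(seed)
  lambda <- rep_len(lambda, n_features)
  log2fc <- rep_len(log2fc, n_features)
  s <- size_factors %||% exp(stats::runif(2L * n_per_group,
                                          log(0.5), log(2)))
  samples <- paste0(rep(c("wildtype", "mutant"), each = n_per_group), "_",
                    seq_len(n_per_group))
  m <- sapply(seq_along(samples), function(j) {
    mu <- s[j] * lambda * if (j > n_per_group) 2 ^ log2fc else 1
    if (phi > 0) stats::rnbinom(n_features, size = 1 / phi, mu = mu)
    else stats::rpois(n_features, mu)
  })
  rownames(m) <- sprintf("g%05d", seq_len(n_features))
  colnames(m) <- samples
  count_matrix(m, rep(c("wildtype", "mutant"), each = n_per_group))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
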