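# independent re-computations used as oracles by several test files

# brute-force orientation rule table
oracle_orientation <- function(fs, fe, fstr, ns, ne, nstr) {
  if (fs < ne && ns < fe) return("overlapping")
  f3 <- if (fstr == "+") fe else fs
  if (nstr == fstr) return("tail_to_head")
  n3 <- if (nstr == "+") ne else ns
  n5 <- if (nstr == "+") ns else ne
  if (abs(n3 - f3) <= abs(n5 - f3)) "tail_to_tail" else "divergent"
}

# literal plain-loop trimmed-mean (TMM) factor computation
oracle_tmm <- function(y, ref) {
  lib <- colSums(y)
  raw <- numeric(ncol(y))
  for (j in seq_len(ncol(y))) {
    obs <- y[, j]; rfc <- y[, ref]
    keep <- obs > 0 & rfc > 0
    obs <- obs[keep]; rfc <- rfc[keep]
    M <- log2((obs / lib[j]) / (rfc / lib[ref]))
    A <- (log2(obs / lib[j]) + log2(rfc / lib[ref])) / 2
    w <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - rfc) / (lib[ref] * rfc)
    if (max(abs(M)) < 1e-6) { raw[j] <- 1; next }
    n <- length(M)
    loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
    loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
    sel <- which(rank(M) >= loM & rank(M) <= hiM &
                   rank(A) >= loA & rank(A) <= hiA)
    raw[j] <- 2 ^ (sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  raw / exp(mean(log(raw)))
}
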