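#' Simulation configuration for synthetic read-through data
#'
#' Bundles every tunable of the generator with validated defaults.  The
#' defaults emulate the study design the pipeline targets: two genotypes
#' (wild-type and a termination-defective mutant), four replicates each,
#' snRNA-sized parent transcripts whose 3' extensions appear only in the
#' mutant, and convergent downstream genes repressed by transcription
#' interference when the extension crosses their TSS.
#'
#' @param contig_length contig length in nt.
#' @param n_loci number of loci to place.
#' @param conditions character vector of condition names; the first is the
#'   reference (wild-type-like) condition.
#' @param replicates_per_condition replicates per condition (study design: 4).
#' @param lambda expected reads per feature (base expression, recycled over
#'   loci); governs both count means and coverage depth.
#' @param coverage_scale depth constant c: expected per-base coverage over a
#'   feature's mature span is \code{c * lambda} (default 0.25, i.e. 50x depth
#'   at \code{lambda = 200}).
#' @param nb_dispersion negative-binomial dispersion phi for counts
#'   (variance = mu + phi * mu^2); 0 selects the Poisson branch.
#' @param readthrough_fraction named numeric vector rho, one entry per
#'   condition: the fraction of polymerases reading through the terminator,
#'   i.e. extension-span coverage relative to the mature span.
#' @param extension_length nt from the parent 3' end to the true extension
#'   endpoint T.
#' @param interference_coefficient kappa in [0, 1]: downstream-gene expression
#'   is multiplied by (1 - kappa) in conditions where the extension covers its
#'   TSS.
#' @param processing_intermediate_fraction pi in [0, 1]: fraction of molecules
#'   extending to a fixed pre-RNA endpoint just past the mature 3' end.
#' @param pre_rna_length nt of the pre-RNA segment beyond the mature 3' end.
#' @param occupancy_shift Delta (nt): 3'-ward displacement of the
#'   termination-zone polymerase peak in non-reference conditions.
#' @param feature_length mature parent transcript length (nt).
#' @param gene_length downstream gene length (nt).
#' @param gene_gap nt between the parent 3' end and the proximal edge of the
#'   downstream gene.
#' @param locus_spacing nt of empty sequence between locus blocks.
#' @param layouts optional character vector (recycled over loci) drawn from
#'   \code{"tail_to_tail"}, \code{"tail_to_head"}, \code{"isolated"}; when
#'   \code{NULL}, layouts are sampled uniformly.
#' @param de_fraction fraction of isolated loci given a planted expression
#'   change (for differential-expression benchmarking).
#' @param de_log2fc log2 fold change of planted changes (sign alternates).
#' @param taper_fraction fraction of the extension span over which coverage
#'   decays linearly to zero at the distal end (0 = rectangular).
#' @param noise logical: Poisson per-base noise on coverage/occupancy tracks
#'   and NB sampling for counts; \code{FALSE} returns exact expectations.
#' @param term_peak_offset nt from the parent 3' end to the wild-type
#'   termination-zone peak center.
#' @param init_peak_height,term_peak_height,peak_sd,body_level occupancy track
#'   shape parameters (signal units / nt).
#' @param seed integer seed; every generator output is a deterministic
#'   function of the config including this seed.
#'
#' @return A validated list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(contig_length = 200000L,
                              n_loci = 20L,
                              conditions = c("wildtype", "mutant"),
                              replicates_per_condition = 4L,
                              lambda = 200,
                              coverage_scale = 0.25,
                              nb_dispersion = 0.05,
                              readthrough_fraction = c(wildtype = 0,
                                                       mutant = 0.8),
                              extension_length = 600L,
                              interference_coefficient = 0.6,
                              processing_intermediate_fraction = 0,
                              pre_rna_length = 50L,
                              occupancy_shift = 150L,
                              feature_length = 150L,
                              gene_length = 300L,
                              gene_gap = 200L,
                              locus_spacing = 2000L,
                              layouts = NULL,
                              de_fraction = 0,
                              de_log2fc = 0,
                              taper_fraction = 0,
                              noise = TRUE,
                              term_peak_offset = 50L,
                              init_peak_height = 100,
                              term_peak_height = 100,
                              peak_sd = 25,
                              body_level = 10,
                              seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(names(cfg$readthrough_fraction)))
    names(cfg$readthrough_fraction) <- conditions
  if (!all(conditions %in% names(cfg$readthrough_fraction)))
    stop("readthrough_fraction must name every condition")
  rho <- cfg$readthrough_fraction[conditions]
  if (any(rho < 0 | rho > 1)) stop("readthrough_fraction must lie in [0, 1]")
  if (cfg$interference_coefficient < 0 || cfg$interference_coefficient > 1)
    stop("interference_coefficient must lie in [0, 1]")
  pi_f <- cfg$processing_intermediate_fraction
  if (pi_f < 0 || pi_f > 1)
    stop("processing_intermediate_fraction must lie in [0, 1]")
  if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  if (any(cfg$lambda <= 0)) stop("lambda must be positive")
  if (cfg$extension_length <= 0)
    stop("extension_length must be positive (T must lie strictly downstream)")
  if (cfg$replicates_per_condition < 1L) stop("need >= 1 replicate")
  if (!is.null(cfg$layouts) &&
      !all(cfg$layouts %in% c("tail_to_tail", "tail_to_head", "isolated")))
    stop("unknown layout name")
  if (cfg$taper_fraction < 0 || cfg$taper_fraction > 1)
    stop("taper_fraction must lie in [0, 1]")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "simulation_config")
}

# sub-seed derivation; kept below 2^31
sim_seed <- function(config, stage, index = 0L) {
  (abs(config$seed) * 48271 + stage * 9973 + index * 101) %% 2147483647L
}

#' Lay out synthetic loci and their ground truth
#'
#' Places \code{n_loci} non-overlapping locus blocks on one contig.  Each
#' block holds a parent transcript (snRNA-like) and, depending on layout, a
#' downstream gene: \emph{tail_to_tail} puts the gene on the opposite strand
#' with its TSS (5'-most base in its own orientation) inside the parent's
#' extension span, so read-through crosses it; \emph{tail_to_head} puts a
#' tandem gene on the same strand whose TSS caps the callable extension;
#' \emph{isolated} has no neighbor.  Minus-strand loci are exact mirror
#' images of the plus-strand construction.
#'
#' @param config a \code{\link{simulation_config}}.
#' @return A list with elements \code{features} (a
#'   \code{\link{feature_table}} of parents and downstream genes) and
#'   \code{truth} (layouts, true extension endpoints, expected call
#'   intervals, TSS positions, per-condition expression multipliers, true
#'   log2 fold changes, and planted interference pairs).
#' @export
simulate_locus_set <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_loci
  Lm <- config$feature_length
  Le <- config$extension_length
  Lg <- config$gene_length
  gap <- config$gene_gap
  block <- Lm + max(Le, gap + Lg) + config$locus_spacing
  if (n > 0L && n * block > config$contig_length)
    stop(sprintf("contig too short: %d loci need %d nt, have %d",
                 n, n * block, config$contig_length))
  empty <- feature_table(character(), integer(), integer(), character(),
                         character())
  if (n == 0L) {
    return(list(features = empty,
                truth = list(loci = data.frame(), multiplier = matrix(
                  numeric(), 0, length(config$conditions),
                  dimnames = list(NULL, config$conditions)),
                  lambda = numeric(), log2fc = numeric(),
                  et_true = data.frame(), interference_pairs = data.frame(),
                  config = config)))
  }
  set.seed(sim_seed(config, 1L))
  layouts <- if (is.null(config$layouts)) {
    sample(c("tail_to_tail", "tail_to_head", "isolated"), n, replace = TRUE)
  } else rep_len(config$layouts, n)
  strands <- sample(c("+", "-"), n, replace = TRUE)
  lambda <- rep_len(config$lambda, n)

  # planted DE on isolated loci, alternating sign
  de_pick <- rep(FALSE, n)
  iso <- which(layouts == "isolated")
  if (config$de_fraction > 0 && length(iso) > 0L) {
    k <- round(config$de_fraction * length(iso))
    de_pick[iso[seq_len(min(k, length(iso)))]] <- TRUE
  }

  rows <- list(); truth_rows <- list()
  conds <- config$conditions
  rho <- config$readthrough_fraction[conds]
  for (i in seq_len(n)) {
    b0 <- (i - 1L) * block
    b1 <- b0 + block
    lay <- layouts[i]; str <- strands[i]
    # construct on a local plus-strand axis, then mirror for minus strand
    p <- c(0L, Lm)                          # parent
    e <- c(Lm, Lm + Le)                     # true extension span
    g <- NULL; gstr_local <- NULL
    if (lay == "tail_to_tail") { g <- c(Lm + gap, Lm + gap + Lg); gstr_local <- "-" }
    if (lay == "tail_to_head") { g <- c(Lm + gap, Lm + gap + Lg); gstr_local <- "+" }
    mirror <- function(iv) c(block - iv[2L], block - iv[1L])
    flip <- function(s) if (s == "+") "-" else "+"
    if (str == "-") {
      p <- mirror(p); e <- mirror(e)
      if (!is.null(g)) { g <- mirror(g); gstr_local <- flip(gstr_local) }
    }
    pid <- sprintf("snR%03d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = "chrS", start = b0 + p[1L], end = b0 + p[2L], strand = str,
      feature_id = pid, feature_class = "snRNA", parent_id = NA_character_,
      score = 0, stringsAsFactors = FALSE)
    gid <- NA_character_; tss <- NA_integer_; gstr <- NA_character_
    if (!is.null(g)) {
      gid <- sprintf("GENE%03d", i)
      gstr <- gstr_local
      rows[[length(rows) + 1L]] <- data.frame(
        contig = "chrS", start = b0 + g[1L], end = b0 + g[2L], strand = gstr,
        feature_id = gid, feature_class = "ORF_T", parent_id = NA_character_,
        score = 0, stringsAsFactors = FALSE)
      tss <- b0 + five_prime(g[1L], g[2L], gstr)
    }
    truth_rows[[i]] <- data.frame(
      locus = i, layout = lay, parent_id = pid, gene_id = gid,
      strand = str, parent_start = b0 + p[1L], parent_end = b0 + p[2L],
      ext_start = b0 + e[1L], ext_end = b0 + e[2L],
      gene_strand = gstr, gene_tss = tss, de_planted = de_pick[i],
      stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, rows)
  class(features) <- c("feature_table", "data.frame")
  validate_feature_table(features)
  loci <- do.call(rbind, truth_rows)

  # TSS covered by the extension?  tail_to_tail genes sit inside the
  # extension span by construction; tail_to_head TSSs cap the call instead.
  ext_covers_tss <- loci$layout == "tail_to_tail" &
    !is.na(loci$gene_tss) &
    loci$gene_tss >= pmin(loci$ext_start, loci$ext_end) &
    loci$gene_tss < pmax(loci$ext_start, loci$ext_end)

  ids <- features$feature_id
  mult <- matrix(1, nrow = length(ids), ncol = length(conds),
                 dimnames = list(ids, conds))
  lam <- stats::setNames(rep(0, length(ids)), ids)
  lam[loci$parent_id] <- lambda
  gene_rows <- !is.na(loci$gene_id)
  lam[loci$gene_id[gene_rows]] <- lambda[gene_rows]
  for (ci in seq_along(conds)) {
    interfered <- ext_covers_tss & rho[ci] > 0
    mult[loci$gene_id[interfered & gene_rows], ci] <-
      1 - config$interference_coefficient
  }
  # planted DE multipliers on isolated parents, alternating direction
  de_loci <- which(loci$de_planted)
  if (length(de_loci)) {
    fc <- 2 ^ (config$de_log2fc * rep_len(c(1, -1), length(de_loci)))
    for (k in seq_along(de_loci)) {
      for (ci in seq_along(conds)[-1L]) {
        mult[loci$parent_id[de_loci[k]], ci] <- fc[k]
      }
    }
  }
  ref <- conds[1L]
  log2fc <- if (length(conds) >= 2L) {
    log2(mult[, conds[2L]] / mult[, ref])
  } else stats::setNames(rep(0, length(ids)), ids)

  # true ET intervals per condition (where read-through exists), plus the
  # interval the caller is expected to report (tail_to_head capped at TSS)
  et_rows <- list()
  for (ci in seq_along(conds)) {
    if (rho[ci] <= 0) next
    for (j in seq_len(nrow(loci))) {
      s <- loci$ext_start[j]; e <- loci$ext_end[j]
      cs <- s; ce <- e
      if (loci$layout[j] == "tail_to_head") {
        if (loci$strand[j] == "+") ce <- min(ce, loci$gene_tss[j])
        else cs <- max(cs, loci$gene_tss[j])
      }
      et_rows[[length(et_rows) + 1L]] <- data.frame(
        parent_id = loci$parent_id[j], condition = conds[ci],
        start = s, end = e, call_start = cs, call_end = ce,
        stringsAsFactors = FALSE)
    }
  }
  et_true <- if (length(et_rows)) do.call(rbind, et_rows) else data.frame()
  ipairs <- loci[ext_covers_tss & gene_rows,
                 c("parent_id", "gene_id", "layout")]
  list(features = features,
       truth = list(loci = loci, multiplier = mult, lambda = lam,
                    log2fc = log2fc, et_true = et_true,
                    interference_pairs = ipairs,
                    ext_covers_tss = stats::setNames(ext_covers_tss,
                                                     loci$parent_id),
                    config = config))
}

#' Simulate strand-specific coverage for one sample
#'
#' Expected per-base coverage is \code{c * lambda} over a parent's mature
#' span, \code{c * lambda * rho[condition]} over its extension span, plus
#' \code{c * lambda * pi} over the pre-RNA segment; downstream genes get
#' \code{c * lambda_g * m} where the multiplier m encodes interference.  With
#' \code{noise = TRUE} observed coverage is Poisson around this expectation.
#'
#' @param sim output of \code{\link{simulate_locus_set}}.
#' @param condition condition name.
#' @param replicate replicate index (seeds the noise draw).
#' @param config a \code{\link{simulation_config}} (defaults to the one used
#'   to build \code{sim}).
#' @return A list with elements \code{"+"} and \code{"-"}, each a
#'   \code{\link{stranded_coverage}} over the simulated contig.
#' @export
simulate_coverage <- function(sim, condition, replicate = 1L,
                              config = sim$truth$config) {
  loci <- sim$truth$loci
  conds <- config$conditions
  stopifnot(condition %in% conds)
  rho <- config$readthrough_fraction[[condition]]
  cscale <- config$coverage_scale
  L <- config$contig_length
  exp_plus <- numeric(L); exp_minus <- numeric(L)
  add <- function(track, from, to, value) {
    # [from, to) in 0-based coordinates
    if (to > from) track[(from + 1L):to] <- track[(from + 1L):to] + value
    track
  }
  for (j in seq_len(nrow(loci))) {
    lam <- sim$truth$lambda[[loci$parent_id[j]]]
    depth <- cscale * lam
    str <- loci$strand[j]
    tgt <- if (str == "+") "exp_plus" else "exp_minus"
    trk <- get(tgt)
    trk <- add(trk, loci$parent_start[j], loci$parent_end[j], depth)
    es <- min(loci$ext_start[j], loci$ext_end[j])
    ee <- max(loci$ext_start[j], loci$ext_end[j])
    if (rho > 0) {
      if (config$taper_fraction > 0) {
        n_ext <- ee - es
        n_tap <- round(config$taper_fraction * n_ext)
        flat <- depth * rho
        prof <- rep(flat, n_ext)
        if (n_tap > 0)
          prof[(n_ext - n_tap + 1L):n_ext] <-
            flat * seq(1, 0, length.out = n_tap)
        if (str == "-") prof <- rev(prof)
        trk[(es + 1L):ee] <- trk[(es + 1L):ee] + prof
      } else {
        trk <- add(trk, es, ee, depth * rho)
      }
    }
    if (config$processing_intermediate_fraction > 0) {
      pre <- config$pre_rna_length
      if (str == "+") {
        trk <- add(trk, loci$parent_end[j],
                   min(loci$parent_end[j] + pre, L),
                   depth * config$processing_intermediate_fraction)
      } else {
        trk <- add(trk, max(loci$parent_start[j] - pre, 0L),
                   loci$parent_start[j],
                   depth * config$processing_intermediate_fraction)
      }
    }
    assign(tgt, trk)
    if (!is.na(loci$gene_id[j])) {
      glam <- sim$truth$lambda[[loci$gene_id[j]]]
      gm <- sim$truth$multiplier[loci$gene_id[j], condition]
      gtgt <- if (loci$gene_strand[j] == "+") "exp_plus" else "exp_minus"
      gtrk <- get(gtgt)
      g <- sim$features[sim$features$feature_id == loci$gene_id[j], ]
      gtrk <- add(gtrk, g$start, g$end, cscale * glam * gm)
      assign(gtgt, gtrk)
    }
  }
  if (config$noise) {
    ci <- match(condition, conds)
    set.seed(sim_seed(config, 2L, ci * 1000L + replicate))
    exp_plus <- as.numeric(stats::rpois(L, exp_plus))
    exp_minus <- as.numeric(stats::rpois(L, exp_minus))
  }
  list("+" = stranded_coverage("chrS", "+", exp_plus),
       "-" = stranded_coverage("chrS", "-", exp_minus))
}

#' Simulate a replicated count matrix
#'
#' \code{count(f, sample) ~ NB(mean = s_j * lambda_f * m_{f,cond},
#' dispersion = phi)} with per-sample library size factors \code{s_j} drawn
#' log-uniform in [0.5, 2]; \code{phi = 0} selects the Poisson branch, and
#' \code{noise = FALSE} returns rounded expectations.
#'
#' @inheritParams simulate_coverage
#' @return A \code{\link{count_matrix}} with samples named
#'   \code{<condition>_<replicate>}, plus attributes \code{"size_factors"}
#'   and \code{"true_log2fc"}.
#' @export
simulate_counts <- function(sim, config = sim$truth$config) {
  conds <- config$conditions
  nrep <- config$replicates_per_condition
  ids <- sim$features$feature_id
  lam <- sim$truth$lambda[ids]
  samples <- as.vector(t(outer(conds, seq_len(nrep), paste, sep = "_")))
  cond_of <- rep(conds, each = nrep)
  set.seed(sim_seed(config, 3L))
  s <- exp(stats::runif(length(samples), log(0.5), log(2)))
  phi <- config$nb_dispersion
  m <- matrix(0L, length(ids), length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    mu <- s[j] * lam * sim$truth$multiplier[ids, cond_of[j]]
    m[, j] <- if (!config$noise) {
      as.integer(round(mu))
    } else if (phi > 0) {
      stats::rnbinom(length(mu), size = 1 / phi, mu = mu)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  cm <- count_matrix(m, stats::setNames(cond_of, samples))
  attr(cm, "size_factors") <- stats::setNames(s, samples)
  attr(cm, "true_log2fc") <- sim$truth$log2fc
  cm
}

#' Simulate a polymerase-occupancy track for one condition
#'
#' Each parent feature contributes a Gaussian initiation peak at its 5' end,
#' a uniform gene-body level, and a Gaussian termination-zone peak centered
#' \code{term_peak_offset} nt past its 3' end; in non-reference conditions
#' the termination peak center is displaced \code{occupancy_shift} nt further
#' 3' (strand-aware) and the level over the extension span is scaled by
#' \code{(1 + rho[cond]) / (1 + rho[reference])}.
#'
#' @inheritParams simulate_coverage
#' @return A list with elements \code{"+"} and \code{"-"}
#'   (\code{\link{stranded_coverage}}, real-valued).
#' @export
simulate_occupancy <- function(sim, condition, config = sim$truth$config) {
  loci <- sim$truth$loci
  conds <- config$conditions
  stopifnot(condition %in% conds)
  is_ref <- condition == conds[1L]
  rho_c <- config$readthrough_fraction[[condition]]
  rho_ref <- config$readthrough_fraction[[conds[1L]]]
  elev <- (1 + rho_c) / (1 + rho_ref)
  L <- config$contig_length
  tracks <- list("+" = numeric(L), "-" = numeric(L))
  sdp <- config$peak_sd
  gauss <- function(track, center, height) {
    lo <- max(0L, floor(center - 4 * sdp))
    hi <- min(L - 1L, ceiling(center + 4 * sdp))
    if (hi < lo) return(track)
    x <- lo:hi
    track[x + 1L] <- track[x + 1L] +
      height * exp(-((x - center) ^ 2) / (2 * sdp ^ 2))
    track
  }
  for (j in seq_len(nrow(loci))) {
    str <- loci$strand[j]
    p5 <- five_prime(loci$parent_start[j], loci$parent_end[j], str)
    p3 <- three_prime(loci$parent_start[j], loci$parent_end[j], str)
    dir <- if (str == "+") 1L else -1L
    tau <- p3 + dir * config$term_peak_offset
    if (!is_ref) tau <- tau + dir * config$occupancy_shift
    trk <- tracks[[str]]
    trk <- gauss(trk, p5, config$init_peak_height)
    trk <- gauss(trk, tau, config$term_peak_height)
    body <- sort(c(loci$parent_start[j], loci$parent_end[j]))
    if (body[2L] > body[1L])
      trk[(body[1L] + 1L):body[2L]] <-
        trk[(body[1L] + 1L):body[2L]] + config$body_level
    ext <- sort(c(loci$ext_start[j], loci$ext_end[j]))
    if (ext[2L] > ext[1L])
      trk[(ext[1L] + 1L):ext[2L]] <- trk[(ext[1L] + 1L):ext[2L]] +
        0.2 * config$body_level * elev
    tracks[[str]] <- trk
  }
  if (config$noise) {
    ci <- match(condition, conds)
    set.seed(sim_seed(config, 4L, ci))
    tracks <- lapply(tracks, function(v) as.numeric(stats::rpois(L, v)))
  }
  list("+" = stranded_coverage("chrS", "+", tracks[["+"]]),
       "-" = stranded_coverage("chrS", "-", tracks[["-"]]))
}
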