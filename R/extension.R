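#' Parameters for extended-transcript calling
#'
#' Operationalizes "continuous reads on the same strand" as per-base coverage
#' at or above a threshold, tolerating short sub-threshold runs.
#'
#' @param min_coverage theta: per-base coverage (reads) at or above which a
#'   base counts as covered.  Default 5.
#' @param max_gap g: longest run of sub-threshold bases (nt) bridged without
#'   ending the call.  Default 25.
#' @param max_extension hard cap on extension length (nt).  Default 5000,
#'   longer than any extension the method is expected to see.
#' @param min_et_length calls shorter than this (nt) are discarded
#'   (\code{stop_reason = "none_called"}).  Default 25.
#' @return A validated list of class \code{"extension_params"}.
#' @export
extension_params <- function(min_coverage = 5, max_gap = 25L,
                             max_extension = 5000L, min_et_length = 25L) {
  if (min_coverage < 0) stop("min_coverage must be >= 0")
  if (max_gap < 0L) stop("max_gap must be >= 0")
  if (min_et_length < 0L) stop("min_et_length must be >= 0")
  if (max_extension <= min_et_length)
    stop("max_extension must exceed min_et_length")
  structure(list(min_coverage = min_coverage, max_gap = as.integer(max_gap),
                 max_extension = as.integer(max_extension),
                 min_et_length = as.integer(min_et_length)),
            class = "extension_params")
}

#' Classify the orientation of a feature and its nearest downstream neighbor
#'
#' Orientation is judged on the feature's own strand axis.  A neighbor on the
#' opposite strand whose 3' end faces the feature's 3' end is
#' \emph{tail_to_tail} (convergent); a same-strand downstream neighbor is
#' \emph{tail_to_head} (tandem); an opposite-strand neighbor presenting its
#' 5' end is \emph{divergent}; intersecting spans are \emph{overlapping}.
#'
#' @param feature,neighbor single-row \code{\link{feature_table}} entries (or
#'   any list with \code{start}, \code{end}, \code{strand}).  The neighbor
#'   must lie at least partly downstream of the feature's 3' end in the
#'   feature's orientation.
#' @return One of \code{"tail_to_tail"}, \code{"tail_to_head"},
#'   \code{"divergent"}, \code{"overlapping"}.
#' @export
classify_orientation <- function(feature, neighbor) {
  fs <- feature$start; fe <- feature$end; fstr <- feature$strand
  ns <- neighbor$start; ne <- neighbor$end; nstr <- neighbor$strand
  if (fs < ne && ns < fe) return("overlapping")
  f3 <- three_prime(fs, fe, fstr)
  downstream <- if (fstr == "+") ne > f3 else ns < f3
  if (!downstream)
    stop("neighbor is not downstream of the feature's 3' end")
  if (nstr == fstr) return("tail_to_head")
  n3 <- three_prime(ns, ne, nstr)
  n5 <- five_prime(ns, ne, nstr)
  if (abs(n3 - f3) <= abs(n5 - f3)) "tail_to_tail" else "divergent"
}

# nearest annotation at least partly downstream of the feature's 3' end,
# excluding the feature itself and its own ET children
nearest_downstream_neighbor <- function(feature, features,
                                        max_distance = Inf) {
  if (nrow(features) == 0L) return(NULL)
  cand <- features[features$contig == feature$contig &
                     features$feature_id != feature$feature_id &
                     !(features$feature_class == "ET" &
                         !is.na(features$parent_id) &
                         features$parent_id == feature$feature_id), ,
                   drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  f3 <- three_prime(feature$start, feature$end, feature$strand)
  if (feature$strand == "+") {
    keep <- cand$end > f3
    dist <- pmax(0L, cand$start[keep] - f3)
  } else {
    keep <- cand$start < f3
    dist <- pmax(0L, f3 - cand$end[keep])
  }
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0L || min(dist) > max_distance) return(NULL)
  out <- cand[which.min(dist), , drop = FALSE]
  out$distance <- min(dist)
  out
}

#' Call an extended transcript downstream of a feature's 3' end
#'
#' Scans strand-aware downstream from the parent's annotated 3' end and
#' extends while per-base coverage stays at or above
#' \code{params$min_coverage}, bridging sub-threshold runs of at most
#' \code{params$max_gap} nt.  The call ends at the first of: a longer
#' sub-threshold run (\code{coverage_gap}); for tail-to-head neighbors, the
#' neighbor's TSS (\code{downstream_tss}); for intron-hosted parents, the
#' host exon boundary (\code{exon_boundary}); or the
#' \code{max_extension} cap.  Tail-to-tail (convergent) neighbors impose no
#' positional cap: a read-through transcript may cross their TSS, which the
#' interference classifier consumes.  Calls shorter than
#' \code{min_et_length} are reported as \code{none_called} with an empty
#' interval.
#'
#' @param feature single-row \code{\link{feature_table}} entry (the parent).
#' @param coverage a \code{\link{stranded_coverage}} on the feature's strand.
#' @param neighbors a \code{\link{feature_table}} used to find the nearest
#'   downstream annotation (may include the feature itself; it is excluded).
#' @param params an \code{\link{extension_params}}.
#' @param exon_boundary optional 0-based coordinate of the host exon 5'
#'   boundary for intron-hosted parents; the call stops just before it.
#' @return One-row \code{data.frame} of class \code{"extension_call"}:
#'   parent id and span, ET span (\code{et_start == et_end} when none
#'   called), \code{stop_reason}, \code{length}, \code{percent_et}, and the
#'   neighbor orientation used.
#' @export
call_extension <- function(feature, coverage, neighbors = NULL,
                           params = extension_params(),
                           exon_boundary = NULL) {
  stopifnot(inherits(coverage, "stranded_coverage"))
  if (coverage$strand != feature$strand)
    stop("coverage strand does not match feature strand")
  L <- length(coverage$values)
  f3 <- three_prime(feature$start, feature$end, feature$strand)
  orientation <- "none"
  nb <- if (!is.null(neighbors)) {
    nearest_downstream_neighbor(feature, neighbors,
                                max_distance = params$max_extension)
  } else NULL
  if (!is.null(nb)) orientation <- classify_orientation(feature, nb)

  mk_call <- function(et_start, et_end, reason) {
    len <- et_end - et_start
    covered <- len > 0L &&
      sum(coverage$values[(min(feature$start, et_start) + 1L):
                            max(feature$end, et_end)]) > 0
    pct <- if (covered) {
      percent_extension(coverage, c(feature$start, feature$end),
                        c(et_start, et_end))
    } else 0
    out <- data.frame(
      parent = feature$feature_id, contig = feature$contig,
      strand = feature$strand,
      parent_start = feature$start, parent_end = feature$end,
      et_start = et_start, et_end = et_end, stop_reason = reason,
      length = len, percent_et = pct, orientation = orientation,
      stringsAsFactors = FALSE)
    class(out) <- c("extension_call", "data.frame")
    out
  }
  at_edge <- if (feature$strand == "+") f3 >= L else f3 <= 0L
  if (at_edge) {
    warning("feature ", feature$feature_id, " 3' end at contig edge; ",
            "no extension called")
    return(mk_call(f3, f3, "none_called"))
  }

  # positional caps, each with its stop reason
  cap <- params$max_extension
  cap_reason <- "max_extension"
  if (orientation == "tail_to_head") {
    tss <- five_prime(nb$start, nb$end, nb$strand)
    d <- if (feature$strand == "+") tss - f3 else f3 - tss
    if (d >= 0L && d < cap) { cap <- d; cap_reason <- "downstream_tss" }
  }
  if (!is.null(exon_boundary)) {
    d <- if (feature$strand == "+") exon_boundary - f3 else f3 - exon_boundary
    if (d >= 0L && d < cap) { cap <- d; cap_reason <- "exon_boundary" }
  }
  room <- if (feature$strand == "+") L - f3 else f3
  if (room < cap) { cap <- room; cap_reason <- "max_extension" }
  if (cap <= 0L) return(mk_call(f3, f3, "none_called"))

  v <- if (feature$strand == "+") {
    coverage$values[(f3 + 1L):(f3 + cap)]
  } else {
    coverage$values[f3:(f3 - cap + 1L)]
  }
  r <- rle(v >= params$min_coverage)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  gap_runs <- which(!r$values & r$lengths > params$max_gap)
  if (length(gap_runs)) {
    ext_len <- starts[gap_runs[1L]]
    reason <- "coverage_gap"
  } else {
    above <- which(r$values)
    ext_len <- if (length(above)) ends[max(above)] else 0L
    reason <- cap_reason
  }
  if (ext_len < params$min_et_length || ext_len == 0L)
    return(mk_call(f3, f3, "none_called"))
  if (feature$strand == "+") {
    mk_call(f3, f3 + ext_len, reason)
  } else {
    mk_call(f3 - ext_len, f3, reason)
  }
}

#' Call extensions for a set of parent features
#'
#' @param features a \code{\link{feature_table}}; calls are made for rows
#'   whose \code{feature_class} is in \code{parent_classes}.
#' @param coverage list with elements \code{"+"} and \code{"-"}
#'   (\code{\link{stranded_coverage}} for the contig).
#' @param parent_classes feature classes to call extensions for.
#' @inheritParams call_extension
#' @return A \code{data.frame} of stacked \code{\link{call_extension}} rows.
#' @export
call_extensions <- function(features, coverage,
                            parent_classes = c("snRNA", "CUT", "SUT"),
                            params = extension_params()) {
  parents <- features[features$feature_class %in% parent_classes, ,
                      drop = FALSE]
  calls <- lapply(seq_len(nrow(parents)), function(i) {
    f <- parents[i, , drop = FALSE]
    call_extension(f, coverage[[f$strand]], neighbors = features,
                   params = params)
  })
  out <- do.call(rbind, c(calls, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- call_extension(feature_table("x", 0, 1, "+", "x"),
                          stranded_coverage("x", "+", c(0, 0)))[0, ]
  }
  class(out) <- c("extension_call", "data.frame")
  out
}

#' Percent extension: area ratio of ET to full transcript-plus-ET span
#'
#' Computes \code{100 * A(et) / A(parent U et)}, where \code{A} is the sum of
#' per-base coverage over an interval (rectangle rule on the per-base step
#' function).  This is the figure-of-merit used to express how much of a
#' transcript's signal lies in its called 3' extension.
#'
#' @param coverage a \code{\link{stranded_coverage}}.
#' @param parent_interval,et_interval length-2 vectors \code{c(start, end)},
#'   0-based half-open; the ET must abut the parent's 3' end
#'   (\code{et_interval} may be empty, \code{start == end}).
#' @return Percent in [0, 100].  An empty ET gives 0; a zero total area is an
#'   error rather than NaN.
#' @export
percent_extension <- function(coverage, parent_interval, et_interval) {
  area <- function(iv) {
    if (iv[2L] <= iv[1L]) return(0)
    sum(coverage$values[(iv[1L] + 1L):iv[2L]])
  }
  a_et <- area(et_interval)
  if (et_interval[2L] <= et_interval[1L]) a_et <- 0
  a_total <- area(parent_interval) + a_et
  if (a_total == 0)
    stop("zero coverage over parent and ET: percent extension undefined")
  if (et_interval[2L] <= et_interval[1L]) return(0)
  100 * a_et / a_total
}

#' Compare extension calls to reference transcript annotations
#'
#' For each call, reports every reference feature on the same contig and
#' strand that overlaps the parent span, with the length difference
#' (reference length minus parent-plus-ET length) and the Jaccard overlap of
#' the spans.  Used to compare called read-through lengths against
#' independently annotated extended-transcript catalogs (NUTs, CUTs).
#'
#' @param calls an \code{\link{extension_call}} data frame.
#' @param reference a \code{\link{feature_table}} of reference annotations.
#' @return A \code{data.frame} with one row per (call, matched reference);
#'   calls without a match contribute no rows.
#' @export
compare_to_reference <- function(calls, reference) {
  out <- list()
  for (i in seq_len(nrow(calls))) {
    cl <- calls[i, ]
    span <- c(min(cl$parent_start, cl$et_start),
              max(cl$parent_end, cl$et_end))
    hits <- reference[reference$contig == cl$contig &
                        reference$strand == cl$strand &
                        reference$start < cl$parent_end &
                        reference$end > cl$parent_start, , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      rf <- hits[j, ]
      inter <- max(0L, min(span[2L], rf$end) - max(span[1L], rf$start))
      uni <- (span[2L] - span[1L]) + (rf$end - rf$start) - inter
      out[[length(out) + 1L]] <- data.frame(
        parent = cl$parent, reference_id = rf$feature_id,
        reference_class = rf$feature_class,
        call_length = span[2L] - span[1L],
        reference_length = rf$end - rf$start,
        length_delta = (rf$end - rf$start) - (span[2L] - span[1L]),
        jaccard = if (uni > 0) inter / uni else 0,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(parent = character(), reference_id = character(),
               reference_class = character(), call_length = integer(),
               reference_length = integer(), length_delta = integer(),
               jaccard = numeric(), stringsAsFactors = FALSE)
}
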