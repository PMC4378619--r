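#' Normalize an occupancy track
#'
#' \code{per_million} scales the whole track to a total of 1e6; idempotent.
#' \code{window_sum} scales the track so the given analysis window sums to 1.
#'
#' @param track a \code{\link{stranded_coverage}}.
#' @param mode \code{"per_million"} or \code{"window_sum"}.
#' @param window length-2 vector \code{c(start, end)}, 0-based half-open;
#'   required for \code{"window_sum"}.
#' @return The rescaled track.
#' @export
normalize_occupancy <- function(track, mode = c("per_million", "window_sum"),
                                window = NULL) {
  mode <- match.arg(mode)
  if (mode == "per_million") {
    total <- sum(track$values)
    if (total == 0) stop("zero total signal: cannot normalize")
    track$values <- track$values * 1e6 / total
  } else {
    if (is.null(window)) stop("window_sum normalization needs a window")
    wsum <- sum(track$values[(window[1L] + 1L):window[2L]])
    if (wsum == 0) stop("zero signal in window: cannot normalize")
    track$values <- track$values / wsum
  }
  track
}

#' Mutant / wild-type occupancy ratio downstream of a feature's 3' end
#'
#' Sums both tracks over the strand-aware window \code{[3' end, 3' end + W)}
#' and returns their ratio, with a pseudo-signal of 1 added to each sum so
#' the ratio is always defined.  Values above 1 indicate polymerase
#' accumulating past the terminator in the mutant.
#'
#' @param mutant,wildtype \code{\link{stranded_coverage}} tracks, normalized
#'   identically (see \code{\link{normalize_occupancy}}).
#' @param feature single-row \code{\link{feature_table}} entry.
#' @param window_length W, nt (default 500: within the termination zone,
#'   shorter than typical read-through transcripts).
#' @return List with \code{ratio} and the \code{window} used.
#' @export
downstream_occupancy_ratio <- function(mutant, wildtype, feature,
                                       window_length = 500L) {
  L <- length(mutant$values)
  f3 <- three_prime(feature$start, feature$end, feature$strand)
  win <- if (feature$strand == "+") {
    c(f3, min(f3 + window_length, L))
  } else {
    c(max(f3 - window_length, 0L), f3)
  }
  wsum <- function(track) {
    if (win[2L] <= win[1L]) return(0)
    sum(track$values[(win[1L] + 1L):win[2L]])
  }
  list(ratio = (wsum(mutant) + 1) / (wsum(wildtype) + 1), window = win)
}

#' Centroid shift of occupancy between conditions
#'
#' Signal-weighted mean position of the mutant track minus that of the
#' wild-type track within an analysis window, sign-flipped on the minus
#' strand so that positive always means a 3'-ward shift.  Exactly linear
#' under translation of the mutant signal and invariant under positive
#' scaling of either track.
#'
#' @param mutant,wildtype \code{\link{stranded_coverage}} tracks on the same
#'   strand.
#' @param window length-2 vector \code{c(start, end)}, 0-based half-open;
#'   both tracks must have nonzero mass inside it.
#' @return Shift in nt.
#' @export
centroid_shift <- function(mutant, wildtype, window) {
  if (mutant$strand != wildtype$strand)
    stop("tracks are on different strands")
  pos <- window[1L]:(window[2L] - 1L)
  centroid <- function(track) {
    w <- track$values[pos + 1L]
    m <- sum(w)
    if (m == 0) stop("zero mass in analysis window")
    sum(pos * w) / m
  }
  shift <- centroid(mutant) - centroid(wildtype)
  if (mutant$strand == "-") shift <- -shift
  shift
}

#' Occupancy 3'-shift report for a set of features
#'
#' Per feature: the downstream occupancy ratio over \code{[3' end,
#' 3' end + W)} and the centroid shift over an analysis window spanning the
#' termination zone (from 100 nt inside the feature's 3' end to \code{W} nt
#' past it).
#'
#' @inheritParams downstream_occupancy_ratio
#' @param features a \code{\link{feature_table}}; one report row per row.
#' @param mutant,wildtype lists with \code{"+"} and \code{"-"} tracks.
#' @param normalization \code{"per_million"} (applied here) or \code{"none"}
#'   (tracks already comparable).
#' @return \code{data.frame}: feature id, window, ratio, centroid shift.
#' @export
occupancy_shift_report <- function(features, mutant, wildtype,
                                   window_length = 500L,
                                   normalization = c("per_million", "none")) {
  normalization <- match.arg(normalization)
  if (normalization == "per_million") {
    mutant <- lapply(mutant, normalize_occupancy, mode = "per_million")
    wildtype <- lapply(wildtype, normalize_occupancy, mode = "per_million")
  }
  rows <- lapply(seq_len(nrow(features)), function(i) {
    f <- features[i, , drop = FALSE]
    mt <- mutant[[f$strand]]; wt <- wildtype[[f$strand]]
    L <- length(mt$values)
    f3 <- three_prime(f$start, f$end, f$strand)
    ratio <- downstream_occupancy_ratio(mt, wt, f, window_length)
    awin <- if (f$strand == "+") {
      c(max(0L, f3 - 100L), min(L, f3 + window_length))
    } else {
      c(max(0L, f3 - window_length), min(L, f3 + 100L))
    }
    shift <- tryCatch(centroid_shift(mt, wt, awin), error = function(e) NA)
    data.frame(feature_id = f$feature_id,
               window_start = ratio$window[1L],
               window_end = ratio$window[2L],
               downstream_ratio = ratio$ratio,
               centroid_shift = shift,
               normalization = normalization, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
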