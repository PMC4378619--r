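#' Build antisense annotations from ORF coding regions
#'
#' For each ORF-T coding-region feature, emits one feature with identical
#' coordinates, the strand flipped, the id prefixed \code{"AS_"} and class
#' \code{"AS"}.  UTR sub-intervals are deliberately excluded by contract:
#' inputs are taken as CDS-only spans.  Re-applying to already-antisense
#' features (ids starting \code{"AS_"} or class \code{"AS"}) is an error
#' rather than silently producing \code{"AS_AS_"} ids.
#'
#' @param orf_features a \code{\link{feature_table}} of CDS spans.
#' @return A \code{\link{feature_table}} of antisense annotations.
#' @export
make_antisense_annotations <- function(orf_features) {
  if (nrow(orf_features) == 0L) return(orf_features)
  if (any(startsWith(orf_features$feature_id, "AS_")) ||
      any(orf_features$feature_class == "AS"))
    stop("input already contains antisense annotations; refusing to re-apply")
  out <- orf_features
  out$strand <- ifelse(orf_features$strand == "+", "-", "+")
  out$feature_id <- paste0("AS_", orf_features$feature_id)
  out$feature_class <- "AS"
  validate_feature_table(out)
  out
}

#' Pair extension calls with their nearest downstream annotation
#'
#' For each ET call (skipping \code{none_called}), finds the nearest
#' annotation on either strand lying at least partly downstream of the
#' parent's 3' end within \code{max_pair_distance} nt, excluding the parent
#' itself and its own ET, and classifies the pair orientation.  Same-strand
#' (tail-to-head) targets are flagged ambiguous: with strand-specific data,
#' reads over a tandem downstream gene cannot be attributed between the gene
#' and a long read-through transcript.
#'
#' @param et_calls an \code{\link{extension_call}} data frame.
#' @param features a \code{\link{feature_table}} of candidate targets.
#' @param max_pair_distance maximum gap (nt) between the parent 3' end and
#'   the target.
#' @return \code{data.frame}: \code{source}, \code{target},
#'   \code{orientation}, \code{distance}, \code{ambiguous_same_strand}.
#' @export
pair_extensions_with_neighbors <- function(et_calls, features,
                                           max_pair_distance = 1000L) {
  out <- list()
  for (i in seq_len(nrow(et_calls))) {
    cl <- et_calls[i, ]
    if (cl$stop_reason == "none_called") next
    parent <- features[features$feature_id == cl$parent, , drop = FALSE]
    if (nrow(parent) != 1L)
      stop("parent feature not found: ", cl$parent)
    nb <- nearest_downstream_neighbor(parent, features,
                                      max_distance = max_pair_distance)
    if (is.null(nb)) next
    ori <- classify_orientation(parent, nb)
    out[[length(out) + 1L]] <- data.frame(
      source = cl$parent, target = nb$feature_id, orientation = ori,
      distance = nb$distance,
      ambiguous_same_strand = ori == "tail_to_head",
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(source = character(), target = character(),
               orientation = character(), distance = integer(),
               ambiguous_same_strand = logical(), stringsAsFactors = FALSE)
}

#' Classify a candidate transcription-interference pair
#'
#' \code{tss_overlap} is TRUE when the parent-plus-ET span covers the
#' target's TSS base (the target's 5'-most base in its own orientation),
#' optionally widened by an upstream promoter margin.  The verdict is
#' \code{"interference"} only when the TSS is covered \emph{and} the target
#' is down-regulated; a covered TSS without down-regulation is
#' \code{"candidate_no_effect"}; an uncovered TSS is \code{"no_overlap"}
#' regardless of the target's expression.
#'
#' @param pair one row of \code{\link{pair_extensions_with_neighbors}}.
#' @param et_call the matching \code{\link{extension_call}} row.
#' @param de_results a \code{\link{de_analysis}} result containing the
#'   target.
#' @param features a \code{\link{feature_table}} containing the target.
#' @param tss_margin nt of upstream (promoter-side) slack added to the
#'   covered span before testing TSS overlap (default 0: the TSS base itself
#'   must be covered).
#' @return One-row \code{data.frame}: source, target, orientation,
#'   \code{tss_overlap}, target log2fc / fdr / label, \code{verdict},
#'   \code{ambiguous_same_strand}.
#' @export
classify_interference <- function(pair, et_call, de_results, features,
                                  tss_margin = 0L) {
  tgt <- features[features$feature_id == pair$target, , drop = FALSE]
  if (nrow(tgt) != 1L) stop("target feature not found: ", pair$target)
  row <- which(de_results$feature_id == pair$target)
  if (length(row) != 1L)
    stop("target absent from DE results: ", pair$target)
  tss <- five_prime(tgt$start, tgt$end, tgt$strand)
  tss_base <- if (tgt$strand == "+") tss else tss - 1L  # 0-based TSS base
  lo <- min(et_call$parent_start, et_call$et_start)
  hi <- max(et_call$parent_end, et_call$et_end)
  # widen on the target's promoter side
  if (tgt$strand == "+") lo <- lo - tss_margin else hi <- hi + tss_margin
  tss_overlap <- tss_base >= lo && tss_base < hi
  label <- de_results$label[row]
  verdict <- if (!tss_overlap) {
    "no_overlap"
  } else if (label == "down") {
    "interference"
  } else {
    "candidate_no_effect"
  }
  data.frame(source = pair$source, target = pair$target,
             orientation = pair$orientation, tss_overlap = tss_overlap,
             target_log2fc = de_results$log2fc[row],
             target_fdr = de_results$fdr[row], target_de_label = label,
             verdict = verdict,
             ambiguous_same_strand = pair$ambiguous_same_strand,
             stringsAsFactors = FALSE)
}

#' Classify all candidate interference pairs for a set of extension calls
#'
#' @inheritParams pair_extensions_with_neighbors
#' @inheritParams classify_interference
#' @return Stacked \code{\link{classify_interference}} rows.
#' @export
classify_interference_pairs <- function(et_calls, features, de_results,
                                        max_pair_distance = 1000L,
                                        tss_margin = 0L) {
  pairs <- pair_extensions_with_neighbors(et_calls, features,
                                          max_pair_distance)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    cl <- et_calls[et_calls$parent == pairs$source[i], , drop = FALSE]
    classify_interference(pairs[i, ], cl[1L, ], de_results, features,
                          tss_margin)
  })
  if (length(out)) do.call(rbind, out) else
    data.frame(source = character(), target = character(),
               orientation = character(), tss_overlap = logical(),
               target_log2fc = numeric(), target_fdr = numeric(),
               target_de_label = character(), verdict = character(),
               ambiguous_same_strand = logical(), stringsAsFactors = FALSE)
}
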