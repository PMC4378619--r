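#' Construct a feature annotation table
#'
#' Features are stranded genomic intervals with a class label, the common
#' currency of the pipeline.  Coordinates are 0-based half-open (BED
#' convention) on both strands; \code{start < end} always, regardless of
#' strand.  The 3' end of a plus-strand feature is \code{end}, of a
#' minus-strand feature \code{start}.
#'
#' @param contig character vector of contig names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector, each \code{"+"} or \code{"-"}.
#' @param feature_id character vector of unique identifiers.
#' @param feature_class character vector; one of \code{"ORF_T"},
#'   \code{"snRNA"}, \code{"CUT"}, \code{"SUT"}, \code{"NUT"}, \code{"SRT"},
#'   \code{"ET"}, \code{"AS"}, \code{"other"}.
#' @param parent_id optional character vector; required (non-NA) for
#'   \code{"ET"} features, which are extensions of a parent transcript.
#' @param score optional numeric vector carried through BED round-trips.
#'
#' @return A \code{data.frame} of class \code{"feature_table"} with one row
#'   per feature.
#' @export
feature_table <- function(contig, start, end, strand, feature_id,
                          feature_class = "other", parent_id = NA_character_,
                          score = 0) {
  n <- length(contig)
  df <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    feature_id = as.character(feature_id),
    feature_class = rep_len(as.character(feature_class), n),
    parent_id = rep_len(as.character(parent_id), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_feature_table(df)
  class(df) <- c("feature_table", "data.frame")
  df
}

feature_classes <- c("ORF_T", "snRNA", "CUT", "SUT", "NUT", "SRT", "ET", "AS",
                     "other")

validate_feature_table <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$start < 0L) || any(df$end < 0L))
    stop("feature coordinates must be non-negative")
  if (any(df$start >= df$end))
    stop("features must satisfy start < end (0-based half-open): ",
         paste(df$feature_id[df$start >= df$end], collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' for every feature")
  if (anyDuplicated(df$feature_id))
    stop("duplicate feature_id: ",
         paste(unique(df$feature_id[duplicated(df$feature_id)]),
               collapse = ", "))
  if (!all(df$feature_class %in% feature_classes))
    stop("unknown feature_class: ",
         paste(setdiff(df$feature_class, feature_classes), collapse = ", "))
  is_et <- df$feature_class == "ET"
  if (any(is_et & is.na(df$parent_id)))
    stop("ET features must carry a parent_id")
  invisible(df)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d features on %d contig(s)\n",
              nrow(x), length(unique(x$contig))))
  if (nrow(x) > 0L) {
    tab <- table(x$feature_class)
    cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

# strand-aware accessors; on "-" the 3' end is the low coordinate
three_prime <- function(start, end, strand) ifelse(strand == "+", end, start)
five_prime <- function(start, end, strand) ifelse(strand == "+", start, end)

#' Construct a per-base coverage track for one strand of one contig
#'
#' @param contig contig name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param values numeric vector of non-negative per-base signal; its length is
#'   the contig length.  \code{values[i]} covers 0-based position \code{i-1}.
#'
#' @return An object of class \code{"stranded_coverage"}.
#' @export
stranded_coverage <- function(contig, strand, values) {
  stopifnot(length(contig) == 1L, strand %in% c("+", "-"))
  values <- as.numeric(values)
  if (any(is.na(values))) stop("coverage values must not be NA")
  if (any(values < 0)) stop("coverage values must be non-negative")
  structure(list(contig = as.character(contig), strand = strand,
                 values = values),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  cat(sprintf("stranded_coverage: %s(%s), %d nt, total signal %.4g\n",
              x$contig, x$strand, length(x$values), sum(x$values)))
  invisible(x)
}

#' Construct an integer count matrix with condition labels
#'
#' @param counts integer matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids).
#' @param conditions character vector naming the condition of each sample;
#'   either named by sample id or in column order.
#'
#' @return An object of class \code{"count_matrix"}: a list with elements
#'   \code{counts} and \code{conditions} (a named character vector).
#' @export
count_matrix <- function(counts, conditions) {
  counts <- as.matrix(counts)
  if (nrow(counts) > 0L && is.null(rownames(counts)))
    stop("counts must have feature ids as rownames")
  if (is.null(colnames(counts)))
    stop("counts must have sample ids as colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature id in count matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  if (is.null(names(conditions))) {
    if (length(conditions) != ncol(counts))
      stop("conditions must name every sample")
    names(conditions) <- colnames(counts)
  }
  if (!all(colnames(counts) %in% names(conditions)))
    stop("every sample needs a condition: missing ",
         paste(setdiff(colnames(counts), names(conditions)), collapse = ", "))
  conditions <- as.character(conditions[colnames(counts)])
  names(conditions) <- colnames(counts)
  structure(list(counts = counts, conditions = conditions),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  tab <- table(x$conditions)
  cat(sprintf("count_matrix: %d features x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}
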