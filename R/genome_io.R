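#' Read feature annotations from BED6 or GTF
#'
#' BED input is taken as 0-based half-open unchanged; GTF input is converted
#' from 1-based closed coordinates to the internal 0-based half-open
#' convention (start - 1, end unchanged).  Strand is mandatory in both
#' dialects: every record must carry \code{"+"} or \code{"-"}.
#'
#' For GTF input the \code{source}, \code{feature}, \code{score}, \code{frame}
#' and raw \code{attributes} columns are retained so that
#' \code{\link{write_features}} can reproduce the file byte for byte; the
#' feature id is taken from the first \code{gene_id} (falling back to
#' \code{transcript_id}) attribute.
#'
#' @param path path to the annotation file.
#' @param format \code{"bed"} or \code{"gtf"}.
#' @return A \code{\link{feature_table}}.
#' @export
read_features <- function(path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (format == "bed") parse_bed(lines, path) else parse_gtf(lines, path)
}

parse_bed <- function(lines, path) {
  if (length(lines) == 0L) {
    return(feature_table(character(), integer(), integer(), character(),
                         character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop(sprintf("%s: line %d: BED6 requires 6 fields (strand is mandatory)",
                 path, which(nf < 6L)[1L]))
  get <- function(i) vapply(fields, `[[`, "", i)
  start <- suppressWarnings(as.integer(get(2L)))
  end <- suppressWarnings(as.integer(get(3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop(sprintf("%s: line %d: non-integer coordinate", path, bad[1L]))
  strand <- get(6L)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("%s: line %d: strand must be '+' or '-', got '%s'",
                 path, bad[1L], strand[bad[1L]]))
  score <- suppressWarnings(as.numeric(get(5L)))
  bad <- which(is.na(score))
  if (length(bad))
    stop(sprintf("%s: line %d: non-numeric score", path, bad[1L]))
  feature_table(get(1L), start, end, strand, get(4L), score = score)
}

parse_gtf <- function(lines, path) {
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(feature_table(character(), integer(), integer(), character(),
                         character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop(sprintf("%s: line %d: GTF requires 9 tab-separated fields",
                 path, which(nf != 9L)[1L]))
  get <- function(i) vapply(fields, `[[`, "", i)
  start1 <- suppressWarnings(as.integer(get(4L)))
  end1 <- suppressWarnings(as.integer(get(5L)))
  bad <- which(is.na(start1) | is.na(end1) | start1 < 1L)
  if (length(bad))
    stop(sprintf("%s: line %d: bad GTF coordinates", path, bad[1L]))
  strand <- get(7L)
  bad <- which(!strand %in% c("+", "-"))
  if (length(bad))
    stop(sprintf("%s: line %d: strand must be '+' or '-', got '%s'",
                 path, bad[1L], strand[bad[1L]]))
  attrs <- get(9L)
  ids <- gtf_attribute(attrs, "gene_id")
  miss <- is.na(ids)
  ids[miss] <- gtf_attribute(attrs[miss], "transcript_id")
  bad <- which(is.na(ids))
  if (length(bad))
    stop(sprintf("%s: line %d: no gene_id or transcript_id attribute",
                 path, bad[1L]))
  df <- feature_table(get(1L), start1 - 1L, end1, strand, ids)
  df$gtf_source <- get(2L)
  df$gtf_feature <- get(3L)
  df$gtf_score <- get(6L)
  df$gtf_frame <- get(8L)
  df$gtf_attributes <- attrs
  df
}

gtf_attribute <- function(attrs, key) {
  m <- regexpr(paste0(key, ' "([^"]*)"'), attrs)
  out <- rep(NA_character_, length(attrs))
  hit <- m > 0L
  out[hit] <- sub(paste0('.*', key, ' "([^"]*)".*'), "\\1", attrs[hit])
  out
}

#' Write feature annotations as BED6 or GTF
#'
#' Inverse of \code{\link{read_features}}: a read/write round trip reproduces
#' a canonical input byte for byte.
#'
#' @param features a \code{\link{feature_table}}.
#' @param path output path.
#' @param format \code{"bed"} or \code{"gtf"}.
#' @return \code{path}, invisibly.
#' @export
write_features <- function(features, path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  if (format == "bed") {
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                     features$contig, features$start, features$end,
                     features$feature_id, format_num(features$score),
                     features$strand)
  } else {
    src <- features$gtf_source %||% rep("termread", nrow(features))
    feat <- features$gtf_feature %||% rep("transcript", nrow(features))
    score <- features$gtf_score %||% rep(".", nrow(features))
    frame <- features$gtf_frame %||% rep(".", nrow(features))
    attrs <- features$gtf_attributes %||%
      sprintf('gene_id "%s";', features$feature_id)
    lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                     features$contig, src, feat, features$start + 1L,
                     features$end, score, features$strand, frame, attrs)
  }
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

format_num <- function(x) {
  out <- as.character(x)
  whole <- x == round(x) & abs(x) < 1e15
  out[whole] <- sprintf("%d", as.integer(round(x[whole])))
  out
}

#' Read a bedGraph file into per-base coverage tracks
#'
#' Positions not covered by any record are filled with 0.  Records must not
#' overlap and must lie within the declared contig lengths.  Negative values
#' are rejected on the plus strand; on the minus strand they are accepted and
#' negated, supporting the common "stranded bedGraph" dialect that encodes
#' minus-strand signal as negative values.
#'
#' @param path path to a bedGraph (UCSC) file.
#' @param strand the strand this file represents, \code{"+"} or \code{"-"}.
#' @param contig_lengths named integer vector of contig lengths.
#' @return A named list of \code{\link{stranded_coverage}} tracks, one per
#'   contig in \code{contig_lengths}.
#' @export
read_coverage <- function(path, strand, contig_lengths) {
  stopifnot(strand %in% c("+", "-"))
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(names(contig_lengths)) || any(!nzchar(names(contig_lengths))))
    stop("contig_lengths must be named by contig")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  tracks <- lapply(contig_lengths, function(L) numeric(L))
  if (length(lines) > 0L) {
    fields <- strsplit(lines, "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 4L))
      stop(sprintf("%s: line %d: bedGraph requires 4 fields",
                   path, which(nf < 4L)[1L]))
    contig <- vapply(fields, `[[`, "", 1L)
    start <- as.integer(vapply(fields, `[[`, "", 2L))
    end <- as.integer(vapply(fields, `[[`, "", 3L))
    value <- as.numeric(vapply(fields, `[[`, "", 4L))
    if (any(is.na(start) | is.na(end) | is.na(value)))
      stop(path, ": malformed bedGraph record")
    unknown <- setdiff(unique(contig), names(contig_lengths))
    if (length(unknown))
      stop("bedGraph names contig(s) absent from contig_lengths: ",
           paste(unknown, collapse = ", "))
    if (any(end > contig_lengths[contig]))
      stop(path, ": record extends beyond declared contig length")
    if (any(start < 0L) || any(start >= end))
      stop(path, ": record with start < 0 or start >= end")
    if (strand == "+" && any(value < 0))
      stop(path, ": negative coverage value on plus strand")
    value <- abs(value)
    for (ctg in unique(contig)) {
      sel <- contig == ctg
      v <- tracks[[ctg]]
      s <- start[sel]; e <- end[sel]; val <- value[sel]
      ord <- order(s)
      s <- s[ord]; e <- e[ord]; val <- val[ord]
      if (any(s[-1L] < e[-length(e)]))
        stop(path, ": overlapping bedGraph records on ", ctg)
      for (i in seq_along(s)) v[(s[i] + 1L):e[i]] <- val[i]
      tracks[[ctg]] <- v
    }
  }
  out <- lapply(names(tracks), function(ctg)
    stranded_coverage(ctg, strand, tracks[[ctg]]))
  names(out) <- names(tracks)
  out
}

#' Split a stranded bedGraph into plus- and minus-strand tracks
#'
#' Records with non-negative values go to the plus strand, records with
#' negative values (negated) to the minus strand.
#'
#' @inheritParams read_coverage
#' @return A list with elements \code{"+"} and \code{"-"}, each as returned by
#'   \code{\link{read_coverage}}.
#' @export
read_stranded_coverage <- function(path, contig_lengths) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") & !startsWith(lines, "#")
  lines <- lines[keep]
  value <- as.numeric(vapply(strsplit(lines, "[ \t]+"), `[[`, "", 4L))
  tp <- tempfile(fileext = ".bedgraph"); tm <- tempfile(fileext = ".bedgraph")
  on.exit(unlink(c(tp, tm)), add = TRUE)
  writeLines(lines[value >= 0], tp)
  writeLines(lines[value < 0], tm)
  list("+" = read_coverage(tp, "+", contig_lengths),
       "-" = read_coverage(tm, "-", contig_lengths))
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted; adjacent equal values are merged, so the output is
#' the canonical minimal bedGraph for the track.
#'
#' @param track a \code{\link{stranded_coverage}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_coverage <- function(track, path) {
  v <- track$values
  r <- rle(v)
  end <- cumsum(r$lengths)
  start <- end - r$lengths
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", track$contig, start[keep], end[keep],
                   format_num(r$values[keep]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a TSV count table
#'
#' The first column holds feature ids, the header row sample ids.  Entries
#' must be non-negative integers; the offending cell is named otherwise.
#'
#' @param path path to the TSV file.
#' @param conditions optional named character vector mapping sample id to
#'   condition.  When \code{NULL}, conditions are inferred by stripping a
#'   trailing \code{_<replicate>} suffix from each sample id.
#' @return A \code{\link{count_matrix}}.
#' @export
read_counts <- function(path, conditions = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop(sprintf("%s: ragged rows (line %d has %d fields, expected %d)",
                 path, which(nf != nf[1L])[1L] , nf[nf != nf[1L]][1L], nf[1L]))
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                          quote = "")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop(path, ": duplicate feature id: ", ids[duplicated(ids)][1L])
  samples <- colnames(df)[-1L]
  m <- matrix(0L, nrow = nrow(df), ncol = length(samples),
              dimnames = list(ids, samples))
  if (nrow(df) > 0L) {
    for (j in seq_along(samples)) {
      x <- suppressWarnings(as.numeric(df[[j + 1L]]))
      bad <- which(is.na(x) | x != round(x) | x < 0)
      if (length(bad))
        stop(sprintf("%s: non-integer count '%s' at feature %s, sample %s",
                     path, df[[j + 1L]][bad[1L]], ids[bad[1L]], samples[j]))
      m[, j] <- as.integer(x)
    }
  }
  if (is.null(conditions))
    conditions <- stats::setNames(sub("_[0-9]+$", "", samples), samples)
  count_matrix(m, conditions)
}

#' Write a count matrix as TSV
#'
#' @param cm a \code{\link{count_matrix}}.
#' @param path output path.
#' @param id_column header for the feature-id column.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(cm, path, id_column = "feature_id") {
  header <- paste(c(id_column, colnames(cm$counts)), collapse = "\t")
  body <- if (nrow(cm$counts) > 0L) {
    apply(cm$counts, 1L, function(r) paste(r, collapse = "\t"))
  } else character()
  lines <- c(header, if (length(body)) paste(rownames(cm$counts), body,
                                             sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
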