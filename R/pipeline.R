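# flat key/value config dialect: "[section]" headers, "key = value" lines,
# "#" comments.  One of [simulation] or [input] selects the pipeline mode.

config_schema <- function() {
  list(
    run = list(seed = "int", output_dir = "str", log_level = "str"),
    simulation = list(
      contig_length = "int", n_loci = "int",
      replicates_per_condition = "int", lambda = "num",
      coverage_scale = "num", nb_dispersion = "num",
      readthrough_wildtype = "num", readthrough_mutant = "num",
      extension_length = "int", interference_coefficient = "num",
      processing_intermediate_fraction = "num", pre_rna_length = "int",
      occupancy_shift = "int", feature_length = "int", gene_length = "int",
      gene_gap = "int", locus_spacing = "int", layouts = "str",
      de_fraction = "num", de_log2fc = "num", taper_fraction = "num",
      noise = "bool", term_peak_offset = "int", init_peak_height = "num",
      term_peak_height = "num", peak_sd = "num", body_level = "num"),
    input = list(
      features = "file", counts = "file", coverage_plus = "file",
      coverage_minus = "file", occupancy_wildtype_plus = "file",
      occupancy_wildtype_minus = "file", occupancy_mutant_plus = "file",
      occupancy_mutant_minus = "file", contig_lengths = "str",
      conditions = "str"),
    extension = list(min_coverage = "num", max_gap = "int",
                     max_extension = "int", min_et_length = "int",
                     parent_classes = "str"),
    de = list(fold_change = "num", p_max = "num", fdr_max = "num"),
    interference = list(max_pair_distance = "int", tss_margin = "int"),
    occupancy = list(window_length = "int"))
}

#' Validate a pipeline configuration file
#'
#' Parses the flat key/value dialect, reports \emph{every} problem found
#' (unknown sections or keys, non-numeric values, out-of-range parameters,
#' missing input files, both or neither of the \code{[simulation]} /
#' \code{[input]} blocks), and fills defaults for everything left unset.
#'
#' @param path path to the config file.
#' @return A list of class \code{"pipeline_config"} with elements
#'   \code{config} (the fully-defaulted nested configuration) and
#'   \code{errors} (character vector; empty when valid).
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  errors <- character()
  raw <- list()
  section <- "run"
  schema <- config_schema()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- sub("^\\[([^]]+)\\]$", "\\1", ln)
      if (!section %in% names(schema))
        errors <- c(errors, sprintf("line %d: unknown section [%s]",
                                    i, section))
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      errors <- c(errors, sprintf("line %d: expected 'key = value'", i))
      next
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!section %in% names(schema)) next
    if (!key %in% names(schema[[section]])) {
      errors <- c(errors, sprintf("line %d: unknown key '%s' in [%s]",
                                  i, key, section))
      next
    }
    raw[[section]][[key]] <- val
  }

  has_sim <- "simulation" %in% names(raw)
  has_input <- "input" %in% names(raw)
  if (has_sim && has_input)
    errors <- c(errors,
                "config has both [simulation] and [input]; exactly one allowed")
  if (!has_sim && !has_input)
    errors <- c(errors,
                "config needs exactly one of [simulation] or [input]")

  conv <- function(section, key, val) {
    type <- schema[[section]][[key]]
    if (type %in% c("int", "num")) {
      x <- suppressWarnings(as.numeric(val))
      if (is.na(x)) {
        errors <<- c(errors, sprintf("[%s] %s: not a number: '%s'",
                                     section, key, val))
        return(NULL)
      }
      if (type == "int") x <- as.integer(round(x))
      return(x)
    }
    if (type == "bool") {
      if (!tolower(val) %in% c("true", "false")) {
        errors <<- c(errors, sprintf("[%s] %s: expected true/false, got '%s'",
                                     section, key, val))
        return(NULL)
      }
      return(tolower(val) == "true")
    }
    if (type == "file" && !file.exists(val)) {
      errors <<- c(errors, sprintf("[%s] %s: file not found: %s",
                                   section, key, val))
    }
    val
  }
  cfg <- list()
  for (sec in names(raw)) {
    for (key in names(raw[[sec]])) {
      v <- conv(sec, key, raw[[sec]][[key]])
      if (!is.null(v)) cfg[[sec]][[key]] <- v
    }
  }

  # defaults
  defaults <- list(
    run = list(seed = 1L, output_dir = "termread_out", log_level = "info"),
    extension = list(min_coverage = 5, max_gap = 25L, max_extension = 5000L,
                     min_et_length = 25L, parent_classes = "snRNA"),
    de = list(fold_change = 1.5, p_max = 0.05, fdr_max = 0.1),
    interference = list(max_pair_distance = 1000L, tss_margin = 0L),
    occupancy = list(window_length = 500L))
  for (sec in names(defaults)) {
    for (key in names(defaults[[sec]])) {
      if (is.null(cfg[[sec]][[key]]))
        cfg[[sec]][[key]] <- defaults[[sec]][[key]]
    }
  }

  # range checks on the knobs with hard invariants
  chk <- function(cond, msg) if (isTRUE(cond)) errors <<- c(errors, msg)
  chk(cfg$extension$max_gap < 0L, "[extension] max_gap: must be >= 0")
  chk(cfg$extension$min_coverage < 0, "[extension] min_coverage: must be >= 0")
  chk(cfg$extension$max_extension <= cfg$extension$min_et_length,
      "[extension] max_extension: must exceed min_et_length")
  chk(cfg$de$fold_change <= 1, "[de] fold_change: must exceed 1")
  chk(cfg$de$p_max <= 0 || cfg$de$p_max >= 1, "[de] p_max: must be in (0,1)")
  chk(cfg$de$fdr_max <= 0 || cfg$de$fdr_max >= 1,
      "[de] fdr_max: must be in (0,1)")
  chk(cfg$interference$max_pair_distance < 0L,
      "[interference] max_pair_distance: must be >= 0")
  chk(cfg$occupancy$window_length <= 0L,
      "[occupancy] window_length: must be positive")

  cfg$mode <- if (has_sim) "simulation" else "files"
  structure(list(config = cfg, errors = errors),
            class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  if (length(x$errors)) {
    cat("invalid pipeline config:\n")
    cat(paste0("  - ", x$errors, collapse = "\n"), "\n")
  } else {
    cat(sprintf("pipeline config: mode=%s, seed=%d, output=%s\n",
                x$config$mode, x$config$run$seed, x$config$run$output_dir))
  }
  invisible(x)
}

sim_config_from_pipeline <- function(cfg) {
  s <- cfg$simulation %||% list()
  rt <- c(wildtype = s$readthrough_wildtype %||% 0,
          mutant = s$readthrough_mutant %||% 0.8)
  s$readthrough_wildtype <- NULL
  s$readthrough_mutant <- NULL
  if (!is.null(s$layouts))
    s$layouts <- trimws(strsplit(s$layouts, ",")[[1L]])
  do.call(simulation_config,
          c(s, list(readthrough_fraction = rt, seed = cfg$run$seed)))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Run the full read-through analysis pipeline
#'
#' Executes, in order: input loading or simulation; count-based differential
#' expression; extension calling on coverage pooled across replicates of the
#' treatment condition; transcription-interference classification; occupancy
#' 3'-shift metrics (when occupancy tracks are available); then writes all
#' per-module TSV/BED outputs, a summary table, and a machine-readable run
#' manifest.  Any stage error aborts with the stage name and leaves a
#' \code{FAILED} marker next to the partial outputs.  Output bytes are a
#' deterministic function of the config (including its seed).
#'
#' @param config a config-file path or a validated
#'   \code{\link{validate_config}} result.
#' @param output_dir overrides the configured output directory.
#' @return Invisibly, a list with the in-memory results (features, counts,
#'   de, et_calls, interference, occupancy, summary) and the output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (length(config$errors))
    stop("invalid config:\n", paste0("  - ", config$errors, collapse = "\n"))
  cfg <- config$config
  out <- output_dir %||% cfg$run$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  quiet <- identical(cfg$run$log_level, "quiet")
  logmsg <- function(...) if (!quiet) message("[termread] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage ", name, ": ", conditionMessage(e)),
                 file.path(out, "FAILED"))
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  unlink(file.path(out, "FAILED"))
  logmsg("seed = ", cfg$run$seed, ", mode = ", cfg$mode)

  ext_params <- extension_params(cfg$extension$min_coverage,
                                 cfg$extension$max_gap,
                                 cfg$extension$max_extension,
                                 cfg$extension$min_et_length)
  thresholds <- de_thresholds(cfg$de$fold_change, cfg$de$p_max,
                              cfg$de$fdr_max)
  parent_classes <- trimws(strsplit(cfg$extension$parent_classes,
                                    ",")[[1L]])

  occupancy_tracks <- NULL
  if (cfg$mode == "simulation") {
    sim_cfg <- stage("configure", sim_config_from_pipeline(cfg))
    sim <- stage("simulate", simulate_locus_set(sim_cfg))
    features <- sim$features
    counts <- stage("simulate", simulate_counts(sim))
    conds <- sim_cfg$conditions
    treatment <- conds[length(conds)]
    logmsg("simulated ", nrow(features), " features, ",
           sim_cfg$n_loci, " loci")
    pool <- stage("simulate", {
      reps <- lapply(seq_len(sim_cfg$replicates_per_condition),
                     function(r) simulate_coverage(sim, treatment, r))
      list("+" = stranded_coverage("chrS", "+",
             Reduce(`+`, lapply(reps, function(x) x[["+"]]$values))),
           "-" = stranded_coverage("chrS", "-",
             Reduce(`+`, lapply(reps, function(x) x[["-"]]$values))))
    })
    occupancy_tracks <- stage("simulate", list(
      wildtype = simulate_occupancy(sim, conds[1L]),
      mutant = simulate_occupancy(sim, treatment)))
  } else {
    inp <- cfg$input
    contig_lengths <- stage("load", {
      parts <- strsplit(trimws(strsplit(inp$contig_lengths, ",")[[1L]]),
                        ":")
      stats::setNames(as.integer(vapply(parts, `[[`, "", 2L)),
                      vapply(parts, `[[`, "", 1L))
    })
    features <- stage("load", read_features(inp$features, "bed"))
    features$feature_class <- ifelse(
      grepl("^snR", features$feature_id), "snRNA",
      ifelse(grepl("^AS_", features$feature_id), "AS", "ORF_T"))
    counts <- stage("load", read_counts(inp$counts))
    pool <- stage("load", {
      cp <- read_coverage(inp$coverage_plus, "+", contig_lengths)
      cm <- read_coverage(inp$coverage_minus, "-", contig_lengths)
      list("+" = cp[[1L]], "-" = cm[[1L]])
    })
    if (!is.null(inp$occupancy_wildtype_plus)) {
      occupancy_tracks <- stage("load", list(
        wildtype = list(
          "+" = read_coverage(inp$occupancy_wildtype_plus, "+",
                              contig_lengths)[[1L]],
          "-" = read_coverage(inp$occupancy_wildtype_minus, "-",
                              contig_lengths)[[1L]]),
        mutant = list(
          "+" = read_coverage(inp$occupancy_mutant_plus, "+",
                              contig_lengths)[[1L]],
          "-" = read_coverage(inp$occupancy_mutant_minus, "-",
                              contig_lengths)[[1L]])))
    }
  }

  de <- stage("diffexpr", de_analysis(counts, thresholds))
  logmsg("differential expression: ", sum(de$label == "up"), " up, ",
         sum(de$label == "down"), " down of ", nrow(de))

  et_calls <- stage("extension", call_extensions(
    features, pool, parent_classes = parent_classes, params = ext_params))
  logmsg(sum(et_calls$stop_reason != "none_called"), " extension calls")

  interference <- stage("interference", classify_interference_pairs(
    et_calls, features, de,
    max_pair_distance = cfg$interference$max_pair_distance,
    tss_margin = cfg$interference$tss_margin))

  occupancy <- if (!is.null(occupancy_tracks)) {
    stage("occupancy", occupancy_shift_report(
      features[features$feature_class %in% parent_classes, , drop = FALSE],
      occupancy_tracks$mutant, occupancy_tracks$wildtype,
      window_length = cfg$occupancy$window_length))
  } else NULL

  # ---- outputs -----------------------------------------------------------
  stage("write", {
    write_features(features, file.path(out, "features.bed"), "bed")
    write_counts(counts, file.path(out, "counts.tsv"))
    cls <- features$feature_class[match(de$feature_id, features$feature_id)]
    de_out <- cbind(data.frame(feature_id = de$feature_id,
                               feature_class = cls,
                               stringsAsFactors = FALSE),
                    de[, setdiff(colnames(de), "feature_id")])
    write_tsv(de_out, file.path(out, "de_results.tsv"))
    called <- et_calls[et_calls$stop_reason != "none_called", , drop = FALSE]
    bed <- sprintf("%s\t%d\t%d\t%s\t%d\t%s", called$contig, called$et_start,
                   called$et_end, paste0(called$parent, "-ET"),
                   round(called$percent_et * 10), called$strand)
    writeLines(bed, file.path(out, "et_calls.bed"))
    write_tsv(et_calls, file.path(out, "et_calls.tsv"))
    write_tsv(interference, file.path(out, "interference.tsv"))
    if (!is.null(occupancy))
      write_tsv(occupancy, file.path(out, "occupancy.tsv"))

    declass <- table(factor(de$label, c("up", "down", "unchanged")), cls)
    sm <- c(
      sprintf("features\t%d", nrow(features)),
      sprintf("de_up\t%d", sum(de$label == "up")),
      sprintf("de_down\t%d", sum(de$label == "down")),
      sprintf("de_up_%s\t%d", colnames(declass), declass["up", ]),
      sprintf("de_down_%s\t%d", colnames(declass), declass["down", ]),
      sprintf("et_calls_%s\t%d",
              names(table(et_calls$stop_reason)),
              as.integer(table(et_calls$stop_reason))),
      sprintf("interference_%s\t%d",
              names(table(interference$verdict)),
              as.integer(table(interference$verdict))))
    writeLines(c("metric\tvalue", sm), file.path(out, "summary.tsv"))

    files <- c("features.bed", "counts.tsv", "de_results.tsv",
               "et_calls.bed", "et_calls.tsv", "interference.tsv",
               if (!is.null(occupancy)) "occupancy.tsv", "summary.tsv")
    md5 <- tools::md5sum(file.path(out, files))
    manifest <- c(
      sprintf("package_version\t%s",
              as.character(utils::packageVersion("termread"))),
      sprintf("seed\t%d", cfg$run$seed),
      sprintf("mode\t%s", cfg$mode),
      sprintf("md5_%s\t%s", files, unname(md5)))
    writeLines(manifest, file.path(out, "manifest.tsv"))
  })
  logmsg("outputs written to ", out)
  invisible(list(features = features, counts = counts, de = de,
                 et_calls = et_calls, interference = interference,
                 occupancy = occupancy, output_dir = out))
}
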