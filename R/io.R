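#' Read / write a probe-set x chip matrix as tab-delimited text
#'
#' Row keys are probe-set ids, column headers are chip ids; values may be
#' numeric signals or P/M/A call letters.
#'
#' @param path File path.
#' @param mat Matrix with dimnames.
#' @return \code{read_signal_matrix}: the matrix.
#' @export
read_signal_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname read_signal_matrix
#' @export
write_signal_matrix <- function(mat, path) {
  df <- data.frame(probe_set_id = rownames(mat), mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata as CSV
#'
#' Columns: \code{sample_id}, \code{strain} (case/control, or raw strain
#' names remapped through \code{strain_map}), \code{age} (weeks),
#' \code{animal_id}.
#'
#' @param path File path.
#' @param meta Metadata data frame.
#' @param strain_map Named character vector mapping raw strain labels to
#'   \code{"case"}/\code{"control"} (default \code{c(GK = "case", WKY =
#'   "control")}); labels already equal to case/control pass through.
#' @export
read_metadata <- function(path, strain_map = c(GK = "case", WKY = "control")) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta$strain <- map_strain(meta$strain, strain_map)
  check_metadata(meta)
}

#' @rdname read_metadata
#' @export
write_metadata <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

map_strain <- function(x, strain_map) {
  x <- as.character(x)
  hit <- x %in% names(strain_map)
  x[hit] <- strain_map[x[hit]]
  x
}

#' Read an annotation map (probe_set_id, gene_symbol, category) from TSV
#' @param path File path.
#' @export
read_annotation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a long-format physiology table from CSV
#' @param path File path.
#' @param strain_map As in \code{\link{read_metadata}}.
#' @export
read_physio <- function(path, strain_map = c(GK = "case", WKY = "control")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab$strain <- map_strain(tab$strain, strain_map)
  tab
}

#' Read a GEO Series Matrix file
#'
#' Parses the processed form of a GEO series deposit: the
#' \code{!Sample_*} header lines and the expression table between
#' \code{!series_matrix_table_begin} and \code{!series_matrix_table_end}.
#' Strain and age are extracted from \code{!Sample_characteristics_ch1}
#' fields of the form \code{"strain: GK"} and \code{"age: 8 weeks"} (the
#' key vocabulary is configurable).
#'
#' @param path Path to an uncompressed series matrix file.
#' @param strain_map Named map from deposit strain labels to
#'   case/control.
#' @param strain_key,age_key Characteristic keys holding strain and age.
#' @return List with \code{values} (probe-set x sample numeric matrix),
#'   \code{metadata} (sample_id, strain, age, animal_id), and
#'   \code{unmapped} (sample ids whose characteristics could not be
#'   parsed).
#' @export
read_series_matrix <- function(path,
                               strain_map = c(GK = "case", WKY = "control"),
                               strain_key = "strain", age_key = "age") {
  lines <- readLines(path)
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin)
    stop("format error: series matrix table delimiters not found in ", path)
  tab <- utils::read.delim(text = lines[(begin + 1L):(end - 1L)],
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "ID_REF")
    stop("format error at line ", begin + 1L, ": expected ID_REF header")
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$ID_REF
  storage.mode(values) <- "double"

  header <- lines[seq_len(begin - 1L)]
  sample_field <- function(name) {
    rows <- grep(paste0("^!", name, "\t"), header, value = TRUE)
    lapply(rows, function(r) gsub("^\"|\"$", "", strsplit(r, "\t")[[1]][-1]))
  }
  ids <- sample_field("Sample_geo_accession")
  ids <- if (length(ids)) ids[[1]] else colnames(values)
  chars <- sample_field("Sample_characteristics_ch1")
  pick <- function(key) {
    pat <- paste0("^\\s*", key, "\\s*:\\s*")
    vapply(seq_along(ids), function(j) {
      for (row in chars) {
        if (j <= length(row) && grepl(pat, row[j]))
          return(sub(pat, "", row[j]))
      }
      NA_character_
    }, "")
  }
  strain_raw <- pick(strain_key)
  age_raw <- pick(age_key)
  age <- suppressWarnings(as.integer(sub("^([0-9]+).*$", "\\1", age_raw)))
  meta <- data.frame(sample_id = ids,
                     strain = map_strain(strain_raw, strain_map),
                     age = age,
                     animal_id = ids,
                     stringsAsFactors = FALSE)
  unmapped <- ids[is.na(strain_raw) | is.na(age) |
                  !meta$strain %in% c("case", "control")]
  colnames(values) <- ids
  list(values = values, metadata = meta, unmapped = unmapped)
}

#' Pipeline configuration
#'
#' Bundles the stage configurations and file paths for
#' \code{\link{run_screen_pipeline}}.  Serializable to/from YAML via
#' \code{\link{read_pipeline_config}}.
#'
#' @param signal_matrix,probe_level,metadata,calls,annotation Paths to
#'   inputs (any may be \code{NULL} when the corresponding object is
#'   passed directly).
#' @param detection A \code{\link{detection_config}}.
#' @param screen A \code{\link{screen_config}}.
#' @param out_dir Optional output directory for artifact files.
#' @export
pipeline_config <- function(signal_matrix = NULL, probe_level = NULL,
                            metadata = NULL, calls = NULL, annotation = NULL,
                            detection = detection_config(),
                            screen = screen_config(),
                            out_dir = NULL) {
  structure(list(signal_matrix = signal_matrix, probe_level = probe_level,
                 metadata = metadata, calls = calls, annotation = annotation,
                 detection = detection, screen = screen, out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields under \code{detection:} and \code{screen:} override the
#' stage defaults; path fields are taken as-is.
#'
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  det <- do.call(detection_config, y$detection %||% list())
  scr <- do.call(screen_config, y$screen %||% list())
  pipeline_config(signal_matrix = y$signal_matrix, probe_level = y$probe_level,
                  metadata = y$metadata, calls = y$calls,
                  annotation = y$annotation,
                  detection = det, screen = scr, out_dir = y$out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full screening cascade
#'
#' Executes the data-mining flowchart end to end: (A) per-chip
#' 50th-percentile scaling, (B/C) detection calls (computed from
#' probe-level PM/MM input, or ingested precomputed), (D) expression
#' filter, (E) control-median ratio normalization, (F/G) per-age fold
#' ratios, (H) persistence filter — plus the annotation rollup when a map
#' is supplied.  Inputs may be given as in-memory objects or through the
#' paths in \code{config}.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param signal Probe-set x chip matrix (overrides
#'   \code{config$signal_matrix}).
#' @param meta Sample metadata (overrides \code{config$metadata}).
#' @param pairs Probe-level input for \code{\link{detect_calls}}.
#' @param calls A detection matrix or P/M/A call matrix (used instead of
#'   \code{pairs} when the deposit carries precomputed calls).
#' @param annotation Annotation map data frame.
#' @return List of class \code{"screen_pipeline"}: \code{summary} (named
#'   list: n_input, n_expressed, n_survivors, n_case_higher,
#'   n_control_higher), \code{screen} (the \code{screen_result}),
#'   \code{expressed_ids}, \code{rollup} (or NULL), \code{log}
#'   (character, one line per step).
#' @export
run_screen_pipeline <- function(config = pipeline_config(), signal = NULL,
                                meta = NULL, pairs = NULL, calls = NULL,
                                annotation = NULL) {
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  if (is.null(signal)) signal <- read_signal_matrix(config$signal_matrix)
  if (is.null(meta)) meta <- read_metadata(config$metadata)
  meta <- check_metadata(meta, colnames(signal))
  note("A: input %d probe sets x %d chips", nrow(signal), ncol(signal))

  scaled <- scale_to_percentile(signal)
  note("A: per-chip 50th-percentile scaling applied")

  if (is.null(calls)) {
    if (!is.null(pairs)) {
      calls <- detect_calls(pairs, config$detection)
      note("B/C: detection calls computed from probe-level PM/MM input")
    } else if (!is.null(config$calls)) {
      calls <- read_signal_matrix(config$calls)
      note("B/C: precomputed detection calls ingested from %s", config$calls)
    } else stop("no detection calls: supply 'pairs', 'calls', or config$calls")
  } else note("B/C: precomputed detection calls supplied")

  expressed <- expression_filter(calls, meta, config$screen)
  note("D: %d probe sets expressed in either strain", length(expressed))

  ratios <- ratio_to_control(scaled[expressed, , drop = FALSE], meta,
                             epsilon = config$screen$epsilon)
  note("E: normalized to control-strain probe-set medians")

  folds <- age_folds(ratios, meta, config$screen)
  note("F/G: per-age fold ratios computed at %d ages", ncol(folds))

  screen <- persistence_filter(folds, config$screen)
  s <- screen$summary
  note("H: %d survivors (>=%g-fold at >=%d ages): %d case-higher, %d control-higher",
       s$n_survivors, config$screen$fold_threshold, config$screen$min_ages,
       s$n_case_higher, s$n_control_higher)

  roll <- NULL
  if (is.null(annotation) && !is.null(config$annotation))
    annotation <- read_annotation(config$annotation)
  if (!is.null(annotation)) {
    surv_ids <- screen$table$probe_set_id[screen$table$survivor]
    roll <- rollup(surv_ids, annotation)
    note("rollup: %d genes from %d mapped probe sets (%d duplicates, %d unmapped)",
         roll$n_genes, roll$n_mapped, roll$n_duplicate_instances, roll$n_unmapped)
  }

  summary <- list(n_input = nrow(signal),
                  n_expressed = length(expressed),
                  n_survivors = s$n_survivors,
                  n_case_higher = s$n_case_higher,
                  n_control_higher = s$n_control_higher)
  out <- structure(list(summary = summary, screen = screen,
                        expressed_ids = expressed, rollup = roll, log = log),
                   class = "screen_pipeline")
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

#' @export
print.screen_pipeline <- function(x, ...) {
  cat(paste0(x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write pipeline artifacts (survivor table, summary JSON, log)
#' @param result A \code{\link{run_screen_pipeline}} result.
#' @param dir Output directory (created if needed).
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  surv <- result$screen$table[result$screen$table$survivor, , drop = FALSE]
  utils::write.table(surv, file.path(dir, "survivors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(result$log, file.path(dir, "pipeline.log"))
  if (!is.null(result$rollup)) {
    r <- result$rollup
    jsonlite::write_json(list(n_probe_sets = r$n_probe_sets,
                              n_unmapped = r$n_unmapped,
                              n_mapped = r$n_mapped,
                              n_genes = r$n_genes,
                              n_duplicate_instances = r$n_duplicate_instances,
                              category_counts = as.list(r$category_counts)),
                         file.path(dir, "rollup.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
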