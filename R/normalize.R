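#' Per-chip percentile scaling
#'
#' Divides every chip (column) by that chip's 50th percentile computed over
#' its strictly positive signals, so chips are comparable on a common
#' scale.  Zeros are excluded from the percentile so that chips with many
#' unexpressed probe sets are not dragged toward zero.  Idempotent.
#'
#' @param mat Numeric probe-set x chip matrix, non-negative, with dimnames.
#' @param percentile Percentile used as the per-chip scale (default 50).
#' @param exclude_regex Optional regex; probe sets whose id matches (e.g.
#'   \code{"^AFFX"} control probes) are excluded from the percentile
#'   computation but still scaled.
#' @return Matrix of the same shape, each column's positive-value
#'   \code{percentile} equal to 1.
#' @export
scale_to_percentile <- function(mat, percentile = 50, exclude_regex = NULL) {
  stopifnot(is.matrix(mat), all(is.finite(mat)), all(mat >= 0))
  ref_rows <- seq_len(nrow(mat))
  if (!is.null(exclude_regex))
    ref_rows <- ref_rows[!grepl(exclude_regex, rownames(mat))]
  scales <- apply(mat[ref_rows, , drop = FALSE], 2L, function(col) {
    pos <- col[col > 0]
    if (length(pos) == 0L) return(NA_real_)
    stats::quantile(pos, percentile / 100, names = FALSE)
  })
  if (anyNA(scales))
    stop("unnormalizable chip (no positive signals): ",
         paste(colnames(mat)[is.na(scales)], collapse = ", "))
  sweep(mat, 2L, scales, "/")
}

#' Control-strain median-ratio normalization
#'
#' Divides every value of probe set i (both strains, so case and control
#' land on a common ratio scale) by the median of probe set i over all
#' control chips.  Control medians of exactly zero are replaced by
#' \code{epsilon} before division and the affected probe sets flagged in
#' attribute \code{"floored_probes"}.
#'
#' Downstream between-group fold ratios are unchanged by this step (the
#' common reference cancels); it exists to put individual chips on a
#' display scale relative to the control strain.
#'
#' @param mat Percentile-scaled probe-set x chip matrix.
#' @param meta Sample metadata (see \code{\link{read_metadata}}): a data
#'   frame with columns \code{sample_id}, \code{strain} (\code{"case"} /
#'   \code{"control"}), \code{age}, \code{animal_id}.
#' @param epsilon Floor substituted for zero control medians (default
#'   0.01).
#' @return Matrix of ratios, same shape, attribute \code{floored_probes}.
#' @export
ratio_to_control <- function(mat, meta, epsilon = 0.01) {
  meta <- check_metadata(meta, colnames(mat))
  ctrl <- meta$sample_id[meta$strain == "control"]
  if (length(ctrl) == 0L) stop("control group is empty")
  med <- apply(mat[, ctrl, drop = FALSE], 1L, stats::median)
  floored <- med == 0
  med[floored] <- epsilon
  out <- mat / med
  attr(out, "floored_probes") <- rownames(mat)[floored]
  out
}

#' Validate sample metadata against a chip set
#'
#' @param meta Metadata data frame.
#' @param sample_ids Chip identifiers the metadata must cover exactly once
#'   each (default: no cross-check).
#' @return The metadata, with \code{strain} normalized to character.
#' @keywords internal
check_metadata <- function(meta, sample_ids = NULL) {
  need <- c("sample_id", "strain", "age", "animal_id")
  if (!all(need %in% names(meta)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  meta$strain <- as.character(meta$strain)
  if (!all(meta$strain %in% c("case", "control")))
    stop("strain must be 'case' or 'control' (map raw strain names first)")
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, meta$sample_id)
    if (length(missing))
      stop("chips without metadata: ", paste(missing, collapse = ", "))
    meta <- meta[match(sample_ids, meta$sample_id), , drop = FALSE]
  }
  meta
}
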