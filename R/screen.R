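#' Screen configuration
#'
#' Parameters of the differential screen: the expression filter
#' (Present-call counting) and the fold-change persistence filter.
#' Defaults reproduce the published cascade: a probe set must be Present
#' on at least 5 of the 25 chips of either strain to count as expressed,
#' and must show at least a 2-fold difference in the same direction at 3
#' or more of the 5 ages to survive.
#'
#' @param min_present_chips Minimum number of Present calls within a
#'   strain for the expression filter (default 5).
#' @param fold_threshold Minimum per-age fold ratio, > 1 (default 2).
#' @param min_ages Minimum number of qualifying ages in one direction
#'   (default 3).
#' @param combine_rule \code{"either_strain"} (kept if expressed in either
#'   strain; default) or \code{"both_strains"}.
#' @param marginal_as_present Count Marginal calls as Present in the
#'   expression filter (default \code{FALSE}).
#' @param fold_summary Per-(strain, age) summary behind the fold ratio:
#'   \code{"median"} (default) or \code{"mean"}.
#' @param epsilon Floor for zero denominators in fold ratios.
#' @return Object of class \code{"screen_config"}.
#' @export
screen_config <- function(min_present_chips = 5L, fold_threshold = 2,
                          min_ages = 3L,
                          combine_rule = c("either_strain", "both_strains"),
                          marginal_as_present = FALSE,
                          fold_summary = c("median", "mean"),
                          epsilon = 0.01) {
  stopifnot(min_present_chips >= 1, fold_threshold > 1, min_ages >= 1)
  structure(list(min_present_chips = as.integer(min_present_chips),
                 fold_threshold = fold_threshold,
                 min_ages = as.integer(min_ages),
                 combine_rule = match.arg(combine_rule),
                 marginal_as_present = marginal_as_present,
                 fold_summary = match.arg(fold_summary),
                 epsilon = epsilon),
            class = "screen_config")
}

#' Expression filter on detection calls
#'
#' Keeps a probe set if it is Present on at least
#' \code{config$min_present_chips} chips of the case strain and/or the
#' control strain, according to \code{combine_rule}.  This implements the
#' elimination steps that leave only probe sets expressed in the tissue.
#'
#' @param detection A \code{\link{detect_calls}} result, or a bare
#'   character call matrix over P/M/A.
#' @param meta Sample metadata covering every chip column.
#' @param config A \code{\link{screen_config}}.
#' @return Character vector of kept probe-set ids.
#' @export
expression_filter <- function(detection, meta, config = screen_config()) {
  calls <- if (inherits(detection, "detection_matrix")) detection$calls else detection
  stopifnot(is.matrix(calls))
  meta <- check_metadata(meta, colnames(calls))
  present <- calls == "P"
  if (config$marginal_as_present) present <- present | calls == "M"
  count_in <- function(strain) {
    chips <- meta$sample_id[meta$strain == strain]
    if (length(chips) < config$min_present_chips)
      stop("configuration error: strain '", strain, "' has ",
           length(chips), " chips, fewer than min_present_chips = ",
           config$min_present_chips)
    rowSums(present[, chips, drop = FALSE])
  }
  in_case <- count_in("case") >= config$min_present_chips
  in_ctrl <- count_in("control") >= config$min_present_chips
  keep <- if (config$combine_rule == "either_strain") in_case | in_ctrl
          else in_case & in_ctrl
  rownames(calls)[keep]
}

#' Per-age fold ratios between strains
#'
#' For every probe set and age, the ratio of the case-group summary
#' (median by default) to the control-group summary of the
#' percentile-scaled signals.  Invariant to \code{\link{ratio_to_control}}
#' (the common reference cancels), so it may be computed before or after
#' that step.
#'
#' @param mat Percentile-scaled probe-set x chip matrix (optionally
#'   already ratio-normalized).
#' @param meta Sample metadata.
#' @param config A \code{\link{screen_config}} (uses \code{fold_summary}
#'   and \code{epsilon}).
#' @return Numeric probe-set x age matrix of fold ratios; column names are
#'   the sorted ages.  Probe sets whose denominator was floored at any age
#'   are listed in attribute \code{"floored_probes"}.
#' @export
age_folds <- function(mat, meta, config = screen_config()) {
  meta <- check_metadata(meta, colnames(mat))
  ages <- sort(unique(meta$age))
  summarize <- if (config$fold_summary == "median") stats::median else mean
  folds <- matrix(NA_real_, nrow(mat), length(ages),
                  dimnames = list(rownames(mat), as.character(ages)))
  floored <- logical(nrow(mat))
  for (j in seq_along(ages)) {
    case_chips <- meta$sample_id[meta$strain == "case" & meta$age == ages[j]]
    ctrl_chips <- meta$sample_id[meta$strain == "control" & meta$age == ages[j]]
    if (length(case_chips) == 0L || length(ctrl_chips) == 0L)
      stop("design error: no chips for one strain at age ", ages[j])
    num <- apply(mat[, case_chips, drop = FALSE], 1L, summarize)
    den <- apply(mat[, ctrl_chips, drop = FALSE], 1L, summarize)
    zero <- den == 0
    den[zero] <- config$epsilon
    floored <- floored | zero
    folds[, j] <- num / den
  }
  attr(folds, "floored_probes") <- rownames(mat)[floored]
  folds
}

#' Fold-change persistence filter
#'
#' Per age, a probe set counts "up" if its fold ratio is at least
#' \code{fold_threshold} and "down" if at most 1/\code{fold_threshold}.
#' A probe set survives if it qualifies in the \emph{same} direction at
#' \code{min_ages} or more ages; its direction is the side reaching the
#' threshold.  With 5 ages and \code{min_ages = 3} the two directions are
#' mutually exclusive, so every survivor has a single direction and
#' the direction tallies partition the survivor count.
#'
#' @param folds Fold table from \code{\link{age_folds}} (restrict its rows
#'   to the expressed set first if the expression filter applies).
#' @param config A \code{\link{screen_config}}.
#' @return Object of class \code{"screen_result"}: a list with
#'   \code{table} (data frame: probe_set_id, direction, n_up, n_down,
#'   survivor, one fold column per age) and \code{summary} (list with
#'   n_input, n_survivors, n_case_higher, n_control_higher).
#' @export
persistence_filter <- function(folds, config = screen_config()) {
  stopifnot(is.matrix(folds), all(is.finite(folds)))
  f <- config$fold_threshold
  up <- folds >= f
  down <- folds <= 1 / f
  n_up <- rowSums(up)
  n_down <- rowSums(down)
  case_higher <- n_up >= config$min_ages
  control_higher <- n_down >= config$min_ages
  both <- case_higher & control_higher    # possible only if 2*min_ages <= n_ages
  if (any(both))
    warning(sum(both), " probe set(s) qualified in both directions; ",
            "direction set to the side with more qualifying ages")
  direction <- rep("none", nrow(folds))
  direction[case_higher] <- "case_higher"
  direction[control_higher] <- "control_higher"
  direction[both] <- ifelse(n_up[both] >= n_down[both],
                            "case_higher", "control_higher")
  survivor <- case_higher | control_higher
  tab <- data.frame(probe_set_id = rownames(folds),
                    direction = direction,
                    n_up = n_up, n_down = n_down,
                    survivor = survivor,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- cbind(tab, as.data.frame(folds, row.names = NULL))
  structure(list(
    table = tab,
    summary = list(n_input = nrow(folds),
                   n_survivors = sum(survivor),
                   n_case_higher = sum(direction == "case_higher" & survivor),
                   n_control_higher = sum(direction == "control_higher" & survivor))),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("Persistence screen: %d probe sets in, %d survivors ",
                     "(%d case-higher, %d control-higher)\n"),
              s$n_input, s$n_survivors, s$n_case_higher, s$n_control_higher))
  invisible(x)
}
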