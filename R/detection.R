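#' Detection-call configuration
#'
#' Thresholds for the Present/Marginal/Absent detection call.  The defaults
#' are the vendor defaults for the MAS5 detection algorithm: discrimination
#' scores are tested against the offset \code{tau}, and the resulting
#' one-sided signed-rank p-value is cut at \code{alpha1} (Present) and
#' \code{alpha2} (Marginal).
#'
#' @param tau Small positive offset subtracted from each discrimination
#'   score before ranking (dimensionless, in \[0, 1)).
#' @param alpha1 p-value threshold below which a probe set is called
#'   Present.
#' @param alpha2 p-value threshold below which (and at or above
#'   \code{alpha1}) a probe set is called Marginal.
#' @return An object of class \code{"detection_config"}.
#' @export
detection_config <- function(tau = 0.015, alpha1 = 0.04, alpha2 = 0.06) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau >= 0, tau < 1,
            is.numeric(alpha1), is.numeric(alpha2),
            alpha1 > 0, alpha1 < alpha2, alpha2 < 0.5)
  structure(list(tau = tau, alpha1 = alpha1, alpha2 = alpha2),
            class = "detection_config")
}

#' Per-pair discrimination scores
#'
#' Computes the discrimination score (PM - MM) / (PM + MM) for each probe
#' pair.  Pairs whose PM + MM is zero carry no signal at all and are
#' dropped; the number dropped is attached as attribute \code{"n_dropped"}.
#'
#' @param pm,mm Numeric vectors of equal length: perfect-match and
#'   mismatch intensities, finite and non-negative.
#' @return Numeric vector of scores in \[-1, 1\], with attribute
#'   \code{n_dropped}.
#' @examples
#' discrimination_scores(c(200, 120), c(100, 60))
#' @export
discrimination_scores <- function(pm, mm) {
  if (length(pm) != length(mm) || length(pm) < 1L)
    stop("pm and mm must have equal length >= 1")
  if (any(!is.finite(pm)) || any(!is.finite(mm)) || any(pm < 0) || any(mm < 0))
    stop("pm and mm must be finite and non-negative")
  tot <- pm + mm
  keep <- tot > 0
  if (!any(keep))
    stop("no usable probe pairs: every pair has pm + mm = 0")
  scores <- (pm[keep] - mm[keep]) / tot[keep]
  attr(scores, "n_dropped") <- sum(!keep)
  scores
}

## Tail probabilities P(W+ >= w) of the tie-free exact signed-rank null for
## ranks 1..n, cached per n (the common case: continuous scores, no ties).
.signed_rank_cache <- new.env(parent = emptyenv())

.signed_rank_tail_tiefree <- function(n) {
  key <- as.character(n)
  tab <- .signed_rank_cache[[key]]
  if (is.null(tab)) {
    ## counts[w + 1] = number of sign assignments with W+ == w
    counts <- 1
    for (r in seq_len(n)) counts <- c(counts, numeric(r)) + c(numeric(r), counts)
    tab <- rev(cumsum(rev(counts))) / 2^n     # tab[w + 1] = P(W+ >= w)
    .signed_rank_cache[[key]] <- tab
  }
  tab
}

## Exact tail probability with arbitrary (mid)ranks, by generating-function
## convolution over doubled ranks (midranks are multiples of 1/2, so doubled
## ranks are integers).
.signed_rank_tail_exact <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  counts <- 1
  for (r in r2) counts <- c(counts, numeric(r)) + c(numeric(r), counts)
  w2 <- as.integer(round(2 * w))
  sum(counts[seq.int(w2 + 1L, length(counts))]) / 2^length(r2)
}

#' One-sided signed-rank detection p-value
#'
#' Tests H0: median(score - tau) = 0 against the one-sided alternative > 0,
#' the detection statistic behind the Present/Marginal/Absent call.  Zero
#' differences (score exactly equal to \code{tau}) are dropped before
#' ranking; ties in |score - tau| receive midranks.  For \code{n <=
#' exact_limit} remaining scores the exact conditional null distribution of
#' the positive-rank sum over all 2^n sign assignments is used; beyond that
#' a normal approximation with continuity and tie correction.
#'
#' @param scores Numeric vector of discrimination scores.
#' @param tau Offset tested against (default 0.015).
#' @param exact_limit Largest n for which the exact null is enumerated
#'   (default 25; 230-2 probe sets have at most 11 pairs, so the exact path
#'   always applies to realistic input).
#' @return p-value in \[0, 1\].  If every score equals \code{tau} the test
#'   is degenerate: p = 1 with attribute \code{degenerate = TRUE}.
#' @export
detection_pvalue <- function(scores, tau = 0.015, exact_limit = 25L) {
  stopifnot(length(scores) >= 1L, all(is.finite(scores)))
  d <- scores - tau
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(structure(1, degenerate = TRUE))
  ranks <- rank(abs(d))                 # midranks for ties
  w <- sum(ranks[d > 0])
  if (n <= exact_limit) {
    if (all(ranks == round(ranks)) && !anyDuplicated(ranks)) {
      tab <- .signed_rank_tail_tiefree(n)
      return(tab[[as.integer(round(w)) + 1L]])
    }
    return(.signed_rank_tail_exact(ranks, w))
  }
  mu <- n * (n + 1) / 4
  ties <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  stats::pnorm(w - 0.5, mean = mu, sd = sqrt(sigma2), lower.tail = FALSE)
}

#' Present/Marginal/Absent call from a detection p-value
#'
#' @param p Detection p-value(s) in \[0, 1\] (vectorized).
#' @param config A \code{\link{detection_config}}.
#' @return Character vector over \code{"P"}, \code{"M"}, \code{"A"}.
#' @export
detection_call <- function(p, config = detection_config()) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < config$alpha1, "P", ifelse(p < config$alpha2, "M", "A"))
}

#' Detection calls for a full probe-level dataset
#'
#' Runs the discrimination-score / signed-rank / threshold chain on every
#' probe set and chip, producing the call and p-value matrices consumed by
#' the expression filter.
#'
#' @param pairs Probe-level intensities.  Either a long-format data frame
#'   with columns \code{probe_set_id}, \code{probe_index},
#'   \code{sample_id}, \code{pm}, \code{mm}, or a list with two 3-d arrays
#'   \code{pm} and \code{mm} of dimension (probe set, pair, chip) carrying
#'   dimnames on margins 1 and 3.
#' @param config A \code{\link{detection_config}}.
#' @return An object of class \code{"detection_matrix"}: a list with
#'   character matrix \code{calls} and numeric matrix \code{pvalues}, both
#'   probe set x chip.
#' @export
detect_calls <- function(pairs, config = detection_config()) {
  if (is.data.frame(pairs)) pairs <- .pairs_long_to_arrays(pairs)
  pm <- pairs$pm; mm <- pairs$mm
  stopifnot(identical(dim(pm), dim(mm)))
  n_probe <- dim(pm)[1]; n_chip <- dim(pm)[3]
  pv <- matrix(NA_real_, n_probe, n_chip,
               dimnames = list(dimnames(pm)[[1]], dimnames(pm)[[3]]))
  for (i in seq_len(n_probe)) {
    for (c in seq_len(n_chip)) {
      s <- discrimination_scores(pm[i, , c], mm[i, , c])
      pv[i, c] <- detection_pvalue(s, tau = config$tau)
    }
  }
  calls <- matrix(detection_call(pv, config), n_probe, n_chip,
                  dimnames = dimnames(pv))
  structure(list(calls = calls, pvalues = pv), class = "detection_matrix")
}

.pairs_long_to_arrays <- function(df) {
  need <- c("probe_set_id", "probe_index", "sample_id", "pm", "mm")
  if (!all(need %in% names(df)))
    stop("probe-level table must have columns: ", paste(need, collapse = ", "))
  probes <- unique(df$probe_set_id)
  chips <- unique(df$sample_id)
  idx <- unique(df$probe_index)
  dn <- list(probes, idx, chips)
  shape <- c(length(probes), length(idx), length(chips))
  pm <- array(NA_real_, shape, dimnames = dn)
  mm <- array(NA_real_, shape, dimnames = dn)
  i <- cbind(match(df$probe_set_id, probes), match(df$probe_index, idx),
             match(df$sample_id, chips))
  pm[i] <- df$pm
  mm[i] <- df$mm
  if (anyNA(pm) || anyNA(mm))
    stop("probe-level table is ragged: every probe set needs the same pairs on every chip")
  list(pm = pm, mm = mm)
}

#' @export
print.detection_matrix <- function(x, ...) {
  tab <- table(factor(x$calls, levels = c("P", "M", "A")))
  cat(sprintf("Detection matrix: %d probe sets x %d chips (P: %d, M: %d, A: %d)\n",
              nrow(x$calls), ncol(x$calls), tab[["P"]], tab[["M"]], tab[["A"]]))
  invisible(x)
}
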