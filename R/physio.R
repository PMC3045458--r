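#' Derive a ratio variable from two physiology variables
#'
#' Adds per-(animal, age) ratios of two measured variables to a
#' long-format physiology table — e.g. daily food intake per gram body
#' weight, or fat-pad weight as a fraction of body weight.  Rows whose
#' denominator is missing or zero are skipped (and counted in attribute
#' \code{"n_skipped"}).
#'
#' @param table Long-format physiology data frame with columns
#'   \code{animal_id}, \code{strain}, \code{age}, \code{variable},
#'   \code{value}, and optionally \code{unit}.
#' @param numerator,denominator Names of the constituent variables.
#' @param name Name of the derived variable (default
#'   \code{"<numerator>_per_<denominator>"}).
#' @return The table with the derived rows appended.
#' @export
derive_variable <- function(table, numerator, denominator,
                            name = paste0(numerator, "_per_", denominator)) {
  num <- table[table$variable == numerator, ]
  den <- table[table$variable == denominator, ]
  if (nrow(num) == 0L || nrow(den) == 0L)
    stop("variable not found: ", if (nrow(num) == 0L) numerator else denominator)
  key <- function(d) paste(d$animal_id, d$age, sep = "\r")
  m <- match(key(num), key(den))
  usable <- !is.na(m) & den$value[m] != 0
  out <- num[usable, , drop = FALSE]
  out$variable <- name
  out$value <- num$value[usable] / den$value[m[usable]]
  if ("unit" %in% names(table)) {
    u_num <- num$unit[usable][1]; u_den <- den$unit[m[usable]][1]
    out$unit <- paste0(u_num, "/", u_den)
  }
  res <- rbind(table, out)
  attr(res, "n_skipped") <- sum(!usable)
  res
}

#' Censor values at a lower limit of detection
#'
#' Values of \code{variable} below \code{floor} are replaced by
#' \code{floor}; a logical column \code{censored} records which rows were
#' affected (e.g. HbA1c readings at or below the assay's 4\% lower limit
#' of detection).
#'
#' @param table Long-format physiology data frame.
#' @param variable Variable to censor.
#' @param floor Detection floor, finite.
#' @return The table with censored values and a \code{censored} column.
#' @export
censor_floor <- function(table, variable, floor) {
  stopifnot(is.finite(floor))
  if (!"censored" %in% names(table)) table$censored <- FALSE
  sel <- table$variable == variable & table$value < floor
  table$value[sel] <- floor
  table$censored[sel] <- TRUE
  table
}

#' Rank-transformed two-way ANOVA with Tukey post-hoc contrasts
#'
#' The nonparametric workhorse for the longitudinal physiology variables:
#' values of one variable are replaced by their global midranks, a
#' two-factor fixed-effects ANOVA (strain, age, strain x age) is fitted to
#' the ranks, and Tukey's HSD is applied to all strain-x-age cell-mean
#' pairs with the studentized-range critical value for the full number of
#' cells.  Only the same-age strain contrasts are reported as flags (one
#' per age, at the 0.05 and 0.001 levels, mirroring the one- and two-star
#' annotations of longitudinal figures); the full pairwise table is also
#' returned.  Because ranks are invariant to strictly monotone maps of
#' the raw values, so is the entire result.
#'
#' @param table Long-format physiology data frame.
#' @param variable Which variable to analyze.
#' @param levels Significance levels for the per-age flags (default
#'   \code{c(0.05, 0.001)}).
#' @param ranking \code{"global"} (midranks over all observations of the
#'   variable; default) or \code{"within_age"} (midranks within each age).
#' @return Object of class \code{"anova_result"}: \code{pvalues} (strain,
#'   age, interaction), \code{age_flags} (data frame: age, p_adj,
#'   direction, one logical flag column per level), and \code{tukey} (full
#'   pairwise cell table).
#' @export
rank_two_way_anova <- function(table, variable, levels = c(0.05, 0.001),
                               ranking = c("global", "within_age")) {
  ranking <- match.arg(ranking)
  d <- table[table$variable == variable, , drop = FALSE]
  if (nrow(d) == 0L) stop("variable not found: ", variable)
  d$strain <- factor(d$strain)
  d$age <- factor(d$age, levels = sort(unique(d$age)))
  cell_n <- table(d$strain, d$age)
  if (any(cell_n < 2L) || nlevels(d$strain) < 2L || nlevels(d$age) < 2L)
    stop("unbalanced design: every strain x age cell needs >= 2 observations")
  d$r <- if (ranking == "global") rank(d$value)
         else stats::ave(d$value, d$age, FUN = rank)
  fit <- stats::aov(r ~ strain * age, data = d)
  sm <- summary(fit)[[1]]
  pv <- stats::setNames(sm[["Pr(>F)"]][1:3], c("strain", "age", "strain_age"))
  ## Tukey HSD over all cells of the crossed design
  cell_fit <- stats::aov(r ~ cell, data = transform(d, cell = interaction(strain, age, sep = "@")))
  tk <- as.data.frame(stats::TukeyHSD(cell_fit)$cell)
  pair <- strsplit(rownames(tk), "-", fixed = TRUE)
  tk$cell_1 <- vapply(pair, `[`, "", 1L)
  tk$cell_2 <- vapply(pair, `[`, "", 2L)
  rownames(tk) <- NULL
  ages <- levels(d$age)
  strains <- levels(d$strain)
  flags <- data.frame(age = ages, p_adj = NA_real_, direction = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(ages)) {
    c1 <- paste(strains[1], ages[i], sep = "@")
    c2 <- paste(strains[2], ages[i], sep = "@")
    row <- tk[(tk$cell_1 == c1 & tk$cell_2 == c2) |
              (tk$cell_1 == c2 & tk$cell_2 == c1), ]
    flags$p_adj[i] <- row$`p adj`[1]
    med <- tapply(d$value, list(d$strain, d$age), stats::median)
    dm <- med["case", ages[i]] - med["control", ages[i]]
    flags$direction[i] <- if (dm > 0) "case_higher"
                          else if (dm < 0) "control_higher" else "equal"
  }
  for (lv in levels)
    flags[[paste0("flag_", lv)]] <- flags$p_adj < lv
  structure(list(variable = variable, pvalues = pv, age_flags = flags,
                 tukey = tk, ranking = ranking),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Rank two-way ANOVA of '%s' (%s ranking)\n", x$variable, x$ranking))
  cat(sprintf("  p(strain) = %.3g, p(age) = %.3g, p(strain x age) = %.3g\n",
              x$pvalues[1], x$pvalues[2], x$pvalues[3]))
  stars <- ifelse(x$age_flags$p_adj < 0.001, "**",
                  ifelse(x$age_flags$p_adj < 0.05, "*", ""))
  cat("  per-age strain contrasts: ",
      paste0(x$age_flags$age, "wk", stars, collapse = ", "), "\n")
  invisible(x)
}

#' Per-age flag table across several variables
#'
#' Convenience wrapper running \code{\link{rank_two_way_anova}} on each
#' variable and binding the per-age flags into one table, mirroring the
#' asterisk annotations of a panel of longitudinal figures.
#'
#' @param table Long-format physiology data frame.
#' @param variables Variables to analyze (default: all present).
#' @param ... Passed to \code{\link{rank_two_way_anova}}.
#' @return Data frame with columns variable, age, p_adj, direction, flags.
#' @export
physio_flag_table <- function(table, variables = unique(table$variable), ...) {
  do.call(rbind, lapply(variables, function(v) {
    fl <- rank_two_way_anova(table, v, ...)$age_flags
    cbind(variable = v, fl)
  }))
}
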