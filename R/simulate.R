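#' Simulation configuration
#'
#' Parameters of the synthetic two-strain, five-age microarray + physiology
#' study.  The design constants default to the emulated study: 2 strains x
#' 5 ages (4, 8, 12, 16, 20 weeks) x 5 chips per group on the arrays, 6
#' animals per strain per age in the physiology table.  Expression is
#' generated from a lognormal intensity model with additive
#' cross-hybridization background: expressed probe sets draw a baseline
#' log2 intensity, PM = signal + background and MM = background only, each
#' with multiplicative lognormal noise; absent probe sets emit background
#' in both channels, so their discrimination scores hover near zero and
#' they are called Absent.  Differential probe sets have their case-strain
#' signal multiplied (or divided) by \code{effect_fold} in the ages of
#' \code{effect_age_window}.  A per-chip scale drift emulates chip-to-chip
#' brightness differences and is what \code{\link{scale_to_percentile}}
#' removes.
#'
#' @param n_probe_sets Number of probe sets (default 5000; the emulated
#'   chip has 31,099).
#' @param n_pairs_per_probe_set Probe pairs per probe set (default 11).
#' @param ages Age levels in weeks.
#' @param chips_per_group Chips per strain x age group (default 5).
#' @param animals_per_group Animals per strain x age group in the
#'   physiology table (default 6).
#' @param fraction_absent Fraction of probe sets not expressed (default
#'   0.3).
#' @param fraction_differential Fraction of \emph{expressed} probe sets
#'   with a planted strain effect (default 0.04).
#' @param effect_fold True fold of planted effects, > 1 (default 4).
#' @param effect_age_window Ages at which planted effects are active
#'   (default: all ages).
#' @param noise_sd Chip-level measurement noise sd on the log2 scale
#'   (default 0.3).
#' @param baseline_log2_mean,baseline_log2_sd Normal distribution of
#'   expressed probe sets' baseline log2 intensities (defaults 7 and 1).
#' @param background_pm Additive background intensity in the PM/MM
#'   channels (default 30).
#' @param background_signal Additive noise floor in the summarized signal
#'   matrix (default 10), so absent probe sets have a small positive
#'   signal.
#' @param chip_drift_sd Sd of per-chip log2 scale drift (default 0.2).
#' @param physio_noise_sd Named per-variable Gaussian noise sds for the
#'   physiology generator; \code{NULL} uses built-in defaults.
#' @param hba1c_floor Lower limit of detection applied to generated HbA1c
#'   (default 4, percent).
#' @param rng_seed Default seed used when a generation call is not given
#'   one explicitly.
#' @return Object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_probe_sets = 5000L,
                              n_pairs_per_probe_set = 11L,
                              ages = c(4L, 8L, 12L, 16L, 20L),
                              chips_per_group = 5L,
                              animals_per_group = 6L,
                              fraction_absent = 0.3,
                              fraction_differential = 0.04,
                              effect_fold = 4,
                              effect_age_window = NULL,
                              noise_sd = 0.3,
                              baseline_log2_mean = 7,
                              baseline_log2_sd = 1,
                              background_pm = 30,
                              background_signal = 10,
                              chip_drift_sd = 0.2,
                              physio_noise_sd = NULL,
                              hba1c_floor = 4,
                              rng_seed = NULL) {
  if (is.null(effect_age_window)) effect_age_window <- ages
  stopifnot(n_probe_sets >= 1, n_pairs_per_probe_set >= 1,
            fraction_absent >= 0, fraction_absent <= 1,
            fraction_differential >= 0, fraction_differential <= 1,
            effect_fold > 1, all(effect_age_window %in% ages),
            noise_sd >= 0, chips_per_group >= 1, animals_per_group >= 1)
  structure(as.list(environment()), class = "simulation_config")
}

.seed_from <- function(config, seed) {
  if (is.null(seed)) seed <- config$rng_seed
  if (is.null(seed)) stop("a seed is mandatory for every generation call")
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  invisible(seed)
}

.chip_metadata <- function(config) {
  grid <- expand.grid(rep = seq_len(config$chips_per_group),
                      age = config$ages,
                      strain = c("case", "control"),
                      stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("%s_wk%02d_c%d", grid$strain, grid$age, grid$rep),
    strain = grid$strain,
    age = grid$age,
    animal_id = sprintf("%s_wk%02d_a%d", grid$strain, grid$age, grid$rep),
    stringsAsFactors = FALSE)
}

#' Simulate a two-strain, five-age expression dataset with known truth
#'
#' @param config A \code{\link{simulation_config}}.
#' @param seed Integer seed (mandatory here or in the config).
#' @return List with \code{pairs} (list of 3-d \code{pm}/\code{mm} arrays,
#'   probe set x pair x chip), \code{signal} (probe-set x chip matrix with
#'   per-chip scale drift still in place), \code{metadata}, and
#'   \code{truth} (data frame: probe_set_id, is_expressed,
#'   is_differential, direction, true_fold, active_ages).
#' @export
simulate_expression <- function(config = simulation_config(), seed = NULL) {
  .seed_from(config, seed)
  np <- config$n_probe_sets; npair <- config$n_pairs_per_probe_set
  meta <- .chip_metadata(config)
  nc <- nrow(meta)
  probes <- sprintf("ps_%05d", seq_len(np))

  expressed <- stats::runif(np) >= config$fraction_absent
  differential <- expressed & stats::runif(np) < config$fraction_differential
  direction <- ifelse(differential,
                      ifelse(stats::runif(np) < 0.5, "case_higher", "control_higher"),
                      "none")
  base_log2 <- stats::rnorm(np, config$baseline_log2_mean, config$baseline_log2_sd)
  signal0 <- ifelse(expressed, 2^base_log2, 0)

  ## true mean signal per probe set x chip
  M <- matrix(signal0, np, nc, dimnames = list(probes, meta$sample_id))
  active_chip <- meta$strain == "case" & meta$age %in% config$effect_age_window
  if (any(active_chip) && any(differential)) {
    mult <- ifelse(direction == "case_higher", config$effect_fold,
                   1 / config$effect_fold)
    mult[!differential] <- 1
    M[, active_chip] <- M[, active_chip] * mult
  }

  drift <- 2^stats::rnorm(nc, 0, config$chip_drift_sd)
  noise <- function(dims) 2^array(stats::rnorm(prod(dims), 0, config$noise_sd), dims)

  signal <- (M + config$background_signal) * noise(c(np, nc))
  signal <- sweep(signal, 2L, drift, "*")
  dimnames(signal) <- list(probes, meta$sample_id)

  dn <- list(probes, seq_len(npair), meta$sample_id)
  Mp <- aperm(array(M, c(np, nc, npair)), c(1, 3, 2))   # probe x pair x chip
  pm <- (Mp + config$background_pm) * noise(c(np, npair, nc))
  mm <- config$background_pm * noise(c(np, npair, nc))
  drift_arr <- array(rep(drift, each = np * npair), c(np, npair, nc))
  pm <- pm * drift_arr; mm <- mm * drift_arr
  dimnames(pm) <- dn; dimnames(mm) <- dn

  truth <- data.frame(probe_set_id = probes,
                      is_expressed = expressed,
                      is_differential = differential,
                      direction = direction,
                      true_fold = ifelse(differential, config$effect_fold, 1),
                      active_ages = ifelse(differential,
                        paste(config$effect_age_window, collapse = ","), ""),
                      stringsAsFactors = FALSE)
  list(pairs = list(pm = pm, mm = mm), signal = signal,
       metadata = meta, truth = truth)
}

## Built-in strain x age cell-mean trajectories for the physiology
## generator.  Triglyceride means are the study's printed per-age values;
## the other variables follow the published longitudinal shapes: body
## weight diverging from 8 weeks, case fat pads plateauing at 12 weeks,
## case HbA1c rising monotonically from the 4% detection floor, control
## corticosterone flat near 122 ng/ml vs a declining case curve, and case
## leukocyte counts elevated at every age.
.physio_truth <- function() {
  list(
    body_weight    = list(unit = "g",
      control = c(80, 200, 300, 350, 380), case = c(80, 180, 240, 270, 290), sd = 15),
    abdominal_fat  = list(unit = "g",
      control = c(1, 4, 8, 12, 16), case = c(1, 3.5, 4.5, 4.5, 4.2), sd = 0.8),
    food_intake    = list(unit = "g/day",
      control = c(12, 20, 22, 22, 20), case = c(12, 20, 22, 23, 23), sd = 1.2),
    hba1c          = list(unit = "%",
      control = c(3.6, 3.6, 3.6, 3.6, 3.6), case = c(4.2, 6, 8, 10, 11.5), sd = 0.35),
    leukocytes     = list(unit = "cells/ul",
      control = rep(6000, 5), case = rep(12000, 5), sd = 900),
    corticosterone = list(unit = "ng/ml",
      control = rep(122.4, 5), case = c(600, 420, 320, 260, 210), sd = 35),
    leptin         = list(unit = "ng/ml",
      control = c(1, 2, 4, 6, 8), case = c(2, 4, 7, 8, 6), sd = 0.7),
    adiponectin    = list(unit = "ug/ml",
      control = c(10, 9, 8, 7, 6.2), case = c(16, 14, 12, 10, 9), sd = 1),
    triglycerides  = list(unit = "mg/dl",
      control = c(63.9, 92.1, 134.9, 138.1, 117.3),
      case = c(80.6, 92.9, 162.9, 175.5, 190.7), sd = 30))
}

#' Simulate a longitudinal physiology table with known truth
#'
#' Generates per-animal values as strain x age cell mean plus Gaussian
#' noise for nine physiology variables whose built-in trajectories follow
#' the emulated study's longitudinal shapes (see
#' \code{\link{simulation_config}}).  HbA1c is emitted after
#' \code{\link{censor_floor}} at \code{config$hba1c_floor}.  The design is
#' cross-sectional by age: every animal appears at exactly one age.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param seed Integer seed (mandatory here or in the config).
#' @param null_strain If \code{TRUE}, both strains share the control
#'   trajectories (no strain effect anywhere) — for null calibration.
#' @return List with \code{table} (long-format data frame: animal_id,
#'   strain, age, variable, value, unit, censored) and \code{truth} (cell
#'   means: strain, age, variable, mean).
#' @export
simulate_physiology <- function(config = simulation_config(), seed = NULL,
                                null_strain = FALSE) {
  .seed_from(config, seed)
  if (length(config$ages) != 5L)
    stop("built-in physiology trajectories assume the five-age design")
  vars <- .physio_truth()
  rows <- list(); truths <- list()
  for (v in names(vars)) {
    spec <- vars[[v]]
    sd_v <- if (!is.null(config$physio_noise_sd[[v]])) config$physio_noise_sd[[v]]
            else spec$sd
    for (strain in c("case", "control")) {
      means <- if (null_strain) spec$control else spec[[strain]]
      for (j in seq_along(config$ages)) {
        age <- config$ages[j]
        n <- config$animals_per_group
        val <- pmax(stats::rnorm(n, means[j], sd_v), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("%s_wk%02d_a%d", strain, age, seq_len(n)),
          strain = strain, age = age, variable = v, value = val,
          unit = spec$unit, stringsAsFactors = FALSE)
        truths[[length(truths) + 1L]] <- data.frame(
          strain = strain, age = age, variable = v, mean = means[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab <- censor_floor(tab, "hba1c", config$hba1c_floor)
  list(table = tab, truth = do.call(rbind, truths))
}
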