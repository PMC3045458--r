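# Independent oracles and small fixture builders shared across tests.

# Exhaustive sign-flip enumeration of the one-sided signed-rank p-value:
# every one of the 2^n sign assignments of the ranked |score - tau|,
# P(W+ >= observed).  Independent of the package's generating-function path.
.sign_matrices <- new.env(parent = emptyenv())

brute_signed_rank_p <- function(scores, tau = 0.015) {
  d <- scores - tau
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  key <- as.character(n)
  S <- .sign_matrices[[key]]
  if (is.null(S)) {
    S <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    .sign_matrices[[key]] <- S
  }
  W <- as.vector(S %*% r)
  mean(W >= w - 1e-9)
}

# Brute-force persistence screen: per probe set, count qualifying ages in
# each direction with an explicit loop.
brute_screen <- function(folds, f, k) {
  out <- data.frame(probe_set_id = rownames(folds),
                    survivor = FALSE, direction = "none",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(folds))) {
    nu <- 0L; nd <- 0L
    for (j in seq_len(ncol(folds))) {
      if (folds[i, j] >= f) nu <- nu + 1L
      if (folds[i, j] <= 1 / f) nd <- nd + 1L
    }
    if (nu >= k) { out$survivor[i] <- TRUE; out$direction[i] <- "case_higher" }
    else if (nd >= k) { out$survivor[i] <- TRUE; out$direction[i] <- "control_higher" }
  }
  out
}

# Brute-force expression filter: per-probe loop over chips.
brute_expression_filter <- function(calls, meta, m, rule, marginal = FALSE) {
  keep <- character()
  for (i in seq_len(nrow(calls))) {
    counts <- c(case = 0L, control = 0L)
    for (j in seq_len(ncol(calls))) {
      strain <- meta$strain[meta$sample_id == colnames(calls)[j]]
      hit <- calls[i, j] == "P" || (marginal && calls[i, j] == "M")
      if (hit) counts[strain] <- counts[strain] + 1L
    }
    ok <- if (rule == "either_strain") any(counts >= m) else all(counts >= m)
    if (ok) keep <- c(keep, rownames(calls)[i])
  }
  keep
}

# Minimal chip metadata for ad-hoc matrices (2 strains x ages x n chips).
make_meta <- function(chips_per_group = 5, ages = c(4, 8, 12, 16, 20)) {
  grid <- expand.grid(rep = seq_len(chips_per_group), age = ages,
                      strain = c("case", "control"), stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_wk%02d_c%d", grid$strain, grid$age, grid$rep),
             strain = grid$strain, age = grid$age,
             animal_id = sprintf("%s_wk%02d_a%d", grid$strain, grid$age, grid$rep),
             stringsAsFactors = FALSE)
}

# A hand-written GEO series-matrix fixture (3 probe sets x 4 samples).
write_series_matrix_fixture <- function(path) {
  lines <- c(
    '!Series_title\t"synthetic two-strain fixture"',
    '!Sample_geo_accession\t"GSM1"\t"GSM2"\t"GSM3"\t"GSM4"',
    '!Sample_characteristics_ch1\t"strain: GK"\t"strain: GK"\t"strain: WKY"\t"strain: WKY"',
    '!Sample_characteristics_ch1\t"age: 8 weeks"\t"age: 12 weeks"\t"age: 8 weeks"\t"age: 12 weeks"',
    "!series_matrix_table_begin",
    "ID_REF\tGSM1\tGSM2\tGSM3\tGSM4",
    "ps_a\t10.5\t12\t5.25\t6",
    "ps_b\t1\t2\t3\t4",
    "ps_c\t0.5\t0.25\t0.5\t0.75",
    "!series_matrix_table_end")
  writeLines(lines, path)
  path
}

# Annotation map with a prescribed unmapped count and duplicate-gene
# structure for a given survivor set.
make_annotation <- function(survivors, n_unmapped, n_duplicate_instances) {
  n <- length(survivors)
  n_mapped <- n - n_unmapped
  n_genes <- n_mapped - n_duplicate_instances
  stopifnot(n_genes >= 1, n_duplicate_instances <= n_genes)
  sym <- c(rep("UNMAPPED", n_unmapped),
           sprintf("Gene%04d", seq_len(n_genes)),
           sprintf("Gene%04d", seq_len(n_duplicate_instances)))
  cats <- annotation_categories()
  data.frame(probe_set_id = survivors,
             gene_symbol = sym,
             category = ifelse(sym == "UNMAPPED", "EST",
                               cats[1 + (seq_len(n) - 1) %% 9]),
             stringsAsFactors = FALSE)
}
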