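make_physio <- function(fun, ages = c(4, 8, 12, 16, 20), n = 6,
                        variable = "v", unit = "u") {
  rows <- expand.grid(rep = seq_len(n), age = ages,
                      strain = c("case", "control"), stringsAsFactors = FALSE)
  data.frame(animal_id = sprintf("%s_%02d_%d", rows$strain, rows$age, rows$rep),
             strain = rows$strain, age = rows$age, variable = variable,
             value = mapply(fun, rows$strain, rows$age, rows$rep),
             unit = unit, stringsAsFactors = FALSE)
}

test_that("derived ratio variables equal row-wise recomputation", {
  set.seed(91)
  fat <- make_physio(function(s, a, r) runif(1, 2, 8), variable = "fat", unit = "g")
  bw <- make_physio(function(s, a, r) runif(1, 200, 400), variable = "body",
                    unit = "g")
  tab <- rbind(fat, bw)
  out <- derive_variable(tab, "fat", "body")
  der <- out[out$variable == "fat_per_body", ]
  expect_equal(nrow(der), nrow(fat))
  key <- paste(der$animal_id, der$age)
  expect_equal(der$value,
               fat$value[match(key, paste(fat$animal_id, fat$age))] /
               bw$value[match(key, paste(bw$animal_id, bw$age))])
  expect_equal(unique(der$unit), "g/g")

  # worked examples: fat 5 g / body 250 g; intake 20 g/day / body 400 g
  mini <- data.frame(animal_id = c("a", "a", "a"), strain = "case", age = 8,
                     variable = c("fat", "body", "intake"),
                     value = c(5, 250, 20), unit = c("g", "g", "g/day"))
  expect_equal(derive_variable(mini, "fat", "body")$value[4], 5 / 250)
  mini2 <- mini; mini2$value[2] <- 400
  expect_equal(derive_variable(mini2, "intake", "body")$value[4], 0.05)

  # missing / zero denominators are skipped and counted
  bw0 <- bw; bw0$value[1] <- 0
  out0 <- derive_variable(rbind(fat, bw0), "fat", "body")
  expect_equal(attr(out0, "n_skipped"), 1L)
})

test_that("censoring replaces sub-floor values and flags them", {
  tab <- data.frame(animal_id = c("a", "b", "c"), strain = "case", age = 4,
                    variable = "hba1c", value = c(3.2, 5.1, 4.0), unit = "%")
  out <- censor_floor(tab, "hba1c", 4)
  expect_equal(out$value, c(4, 5.1, 4.0))
  expect_equal(out$censored, c(TRUE, FALSE, FALSE))

  set.seed(92)
  raw <- rnorm(500, 4.2, 0.5)
  big <- data.frame(animal_id = seq_along(raw), strain = "case", age = 4,
                    variable = "hba1c", value = raw, unit = "%")
  out <- censor_floor(big, "hba1c", 4)
  expect_equal(sum(out$censored), sum(raw < 4))
})

test_that("identical strains yield no strain effect and no flags", {
  set.seed(93)
  base <- matrix(rnorm(30, 100, 10), 5)
  tab <- make_physio(function(s, a, r) base[match(a, c(4, 8, 12, 16, 20)), r])
  res <- rank_two_way_anova(tab, "v")
  expect_gt(res$pvalues[["strain"]], 0.9)
  expect_false(any(res$age_flags$flag_0.05))
})

test_that("the whole result is invariant under strictly monotone transforms", {
  set.seed(94)
  tab <- make_physio(function(s, a, r) rnorm(1, 50 + 5 * (s == "case"), 8))
  res1 <- rank_two_way_anova(tab, "v")
  tab2 <- tab; tab2$value <- exp(tab$value / 20)
  res2 <- rank_two_way_anova(tab2, "v")
  expect_equal(res1$pvalues, res2$pvalues)
  expect_equal(res1$age_flags$p_adj, res2$age_flags$p_adj)
  expect_equal(res1$age_flags$direction, res2$age_flags$direction)
})

test_that("a massive planted strain shift is flagged at every age", {
  set.seed(95)
  tab <- make_physio(function(s, a, r) rnorm(1, 100 + 100 * (s == "case"), 10))
  res <- rank_two_way_anova(tab, "v")
  expect_true(all(res$age_flags$flag_0.05))
  expect_true(all(res$age_flags$direction == "case_higher"))
  # permutation-test oracle per age: 10,000 strain-label reshuffles
  for (a in c(4, 8, 12, 16, 20)) {
    d <- tab[tab$age == a, ]
    obs <- abs(mean(d$value[d$strain == "case"]) -
               mean(d$value[d$strain == "control"]))
    perm <- replicate(10000, {
      lab <- sample(d$strain)
      abs(mean(d$value[lab == "case"]) - mean(d$value[lab == "control"]))
    })
    expect_lte(mean(perm >= obs), 0.01)
  }
})

test_that("flags are monotone across levels and agree with cell medians", {
  set.seed(96)
  tab <- make_physio(function(s, a, r)
    rnorm(1, 100 + ifelse(s == "case", 3 * a, 0), 15))
  res <- rank_two_way_anova(tab, "v")
  expect_true(all(!res$age_flags$flag_0.001 | res$age_flags$flag_0.05))
  med <- tapply(tab$value, list(tab$strain, tab$age), median)
  for (i in seq_len(5)) {
    if (res$age_flags$flag_0.05[i]) {
      dm <- med["case", i] - med["control", i]
      expect_equal(res$age_flags$direction[i],
                   if (dm > 0) "case_higher" else "control_higher")
    }
  }
})

test_that("empty design cells are rejected", {
  set.seed(97)
  tab <- make_physio(function(s, a, r) rnorm(1))
  tab <- tab[!(tab$strain == "case" & tab$age == 12), ]
  expect_error(rank_two_way_anova(tab, "v"), "unbalanced design")
  expect_error(rank_two_way_anova(tab, "nope"), "variable not found")
})

test_that("within-age ranking is available and also monotone-invariant", {
  set.seed(98)
  tab <- make_physio(function(s, a, r) rnorm(1, 10 * a, 5))
  r1 <- rank_two_way_anova(tab, "v", ranking = "within_age")
  tab2 <- tab; tab2$value <- tab$value^3
  r2 <- rank_two_way_anova(tab2, "v", ranking = "within_age")
  expect_equal(r1$age_flags$p_adj, r2$age_flags$p_adj)
})
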