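test_that("Egger regression detects no asymmetry in an exactly symmetric construction", {
  # constant effect across precisions: points on a line through the origin
  eff <- make_effects(rep(0.3, 3), c(1, 0.5, 0.25))
  eg <- egger_test(eff)
  expect_equal(eg$intercept, 0)
  expect_equal(eg$p, 1)
  expect_equal(eg$slope, 0.3, tolerance = 1e-8)

  expect_error(egger_test(make_effects(c(0, 0.2), c(0.1, 0.2))),
               "at least 3")

  # agrees with metafor's classical (lm-weighted) regression test
  eff26 <- study_effects(table1(), "allele")
  eg26 <- egger_test(eff26)
  ref <- metafor::regtest(metafor::rma(yi = eff26$log_or, vi = eff26$se^2,
                                       method = "DL"),
                          model = "lm", predictor = "sei")
  expect_equal(eg26$p, ref$pval, tolerance = 1e-6)
})

test_that("Kendall tau matches brute-force pair counting and handles ties", {
  kt <- assocmeta:::kendall_tau

  # one concordant, two discordant pairs among k = 3
  ex <- kt(c(2, 3, 1), c(1, 2, 3))
  expect_equal(ex$tau, -1 / 3, tolerance = 1e-12)
  expect_equal(ex$concordant, 1)
  expect_equal(ex$discordant, 2)

  # untied data: matches base R's Kendall correlation
  set.seed(51)
  for (i in 1:10) {
    k <- sample(4:12, 1)
    x <- rnorm(k); y <- rnorm(k)
    expect_equal(kt(x, y)$tau, cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
  }

  # all-tied second variable: no orderable pairs, tau = 0
  tied <- kt(rnorm(6), rep(1, 6))
  expect_equal(tied$tau, 0)
})

test_that("Begg's rank correlation behaves under ties and matches metafor", {
  eff <- study_effects(table1(), "allele")
  bg <- begg_test(eff)
  ref <- metafor::ranktest(eff$log_or, eff$se^2)
  expect_equal(bg$tau, unname(ref$tau), tolerance = 1e-10)
  # p-value against the continuity-corrected normal approximation
  wi <- 1 / eff$se^2
  ystar <- (eff$log_or - sum(wi * eff$log_or) / sum(wi)) /
    sqrt(eff$se^2 - 1 / sum(wi))
  cref <- suppressWarnings(cor.test(ystar, eff$se^2, method = "kendall",
                                    exact = FALSE, continuity = TRUE))
  expect_equal(bg$p, cref$p.value, tolerance = 1e-6)

  # equal variances: deviate/variance pairs are all tied in v -> tau 0
  same_v <- make_effects(rnorm(5, 0, 0.2), rep(0.2, 5))
  expect_warning(b0 <- begg_test(same_v), NA)
  expect_equal(b0$tau, 0)
  expect_equal(b0$p, 1)

  expect_error(begg_test(make_effects(c(0, 1), c(1, 1))), "at least 3")
})

test_that("funnel coordinates carry one point per study", {
  one <- funnel_data(make_effects(0.2, 0.1))
  expect_equal(nrow(one), 1)
  f26 <- funnel_data(study_effects(table1(), "allele"))
  expect_equal(nrow(f26), 26)
  expect_equal(attr(f26, "se_axis"), "reversed")
})

test_that("leave-one-out influence reproduces identities and shrinks with omitted weight", {
  # identical studies: every omission reproduces the full pooled OR
  same <- rbind(geno_row("a", c(30, 50, 20), c(25, 50, 25)),
                geno_row("b", c(30, 50, 20), c(25, 50, 25)),
                geno_row("c", c(30, 50, 20), c(25, 50, 25)))
  inf_same <- influence_analysis(as_study_table(same))
  expect_equal(inf_same$results$or, rep(inf_same$full$or_, 3),
               tolerance = 1e-10)
  expect_false(inf_same$crosses_null)

  # k = 2: each omission is the other study alone
  two <- influence_analysis_effects <- make_effects(c(0, 0.2), c(0.1, 0.1))
  # build via a table so the public interface is exercised
  t2 <- rbind(geno_row("a", c(30, 50, 20), c(25, 50, 25)),
              geno_row("b", c(20, 50, 30), c(25, 50, 25)))
  inf2 <- influence_analysis(as_study_table(t2))
  e2 <- study_effects(as_study_table(t2))
  expect_equal(inf2$results$or, rev(e2$or), tolerance = 1e-10)

  # |Delta| from omitting a study shrinks monotonically as its variance grows
  base <- make_effects(rep(0, 5), rep(0.1, 5))
  deltas <- vapply(c(0.2, 0.5, 1, 2, 5), function(s) {
    eff <- rbind(base, make_effects(0.5, s))
    eff$study_id <- sprintf("s%02d", seq_len(nrow(eff)))
    full <- pool_inverse_variance(eff)$log_or
    abs(full - pool_inverse_variance(base)$log_or)
  }, 0)
  expect_true(all(diff(deltas) < 0))
})

test_that("the shipped reconstruction is stable under single-study deletion", {
  infl <- influence_analysis(table1(), "allele", "DL_random")
  expect_equal(nrow(infl$results), 26)
  expect_true(all(infl$results$or > 1))
  expect_false(infl$crosses_null)
})
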