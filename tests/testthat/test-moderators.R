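test_that("between-subgroup heterogeneity matches hand computation and decomposes Q", {
  # one study per group, weights 100, overall 0.2: Q_between = 2
  tab <- rbind(geno_row("w1", c(30, 50, 20), c(25, 50, 25),
                        ethnicity = "European"),
               geno_row("e1", c(30, 50, 20), c(25, 50, 25),
                        ethnicity = "Chinese"))
  direct <- local({
    eff <- study_effects(as_study_table(tab))
    wi <- 1 / eff$se^2
    mu <- sum(wi * eff$log_or) / sum(wi)
    sum(wi * (eff$log_or - mu)^2)
  })
  sg <- subgroup_analysis(as_study_table(tab), group_by = "ethnic_group")
  expect_equal(sg$q_between, direct, tolerance = 1e-12)
  expect_equal(sg$q_between, 0, tolerance = 1e-12)  # identical groups

  # two synthetic one-study groups with y = 0.1, 0.3 and v = 0.01
  # (hand value: overall 0.2, weights 100 -> Q_between = 2)
  eff2 <- make_effects(c(0.1, 0.3), c(0.1, 0.1))
  wi <- 1 / eff2$se^2
  mu_all <- sum(wi * eff2$log_or) / sum(wi)
  qb <- sum(wi * (eff2$log_or - mu_all)^2)
  expect_equal(qb, 2, tolerance = 1e-12)

  # Q decomposition identity on simulated collections
  for (s in 1:3) {
    st <- simulate_meta(simulation_config(k = 24, seed = 200 + s))
    rep_eth <- subgroup_analysis(st, group_by = "ethnic_group")
    expect_equal(rep_eth$q_total,
                 sum(rep_eth$q_within) + rep_eth$q_between,
                 tolerance = 1e-8)
    rep_des <- subgroup_analysis(st, group_by = "design")
    expect_equal(rep_des$q_total,
                 sum(rep_des$q_within) + rep_des$q_between,
                 tolerance = 1e-8)
  }
})

test_that("single-group input gives zero between-subgroup heterogeneity", {
  tab <- rbind(geno_row("a", c(30, 50, 20), c(25, 50, 25)),
               geno_row("b", c(35, 45, 20), c(25, 50, 25)))
  sg <- subgroup_analysis(as_study_table(tab), group_by = "ethnic_group")
  expect_equal(length(sg$groups), 1)
  expect_equal(sg$q_between, 0, tolerance = 1e-12)
})

test_that("meta-regression reduces to DL pooling and recovers exact linear structure", {
  eff <- study_effects(table1(), "allele")
  mr0 <- meta_regression(eff)
  dl <- pool_dersimonian_laird(eff)
  expect_equal(mr0$coefficients$estimate, dl$log_or, tolerance = 1e-12)
  expect_equal(mr0$coefficients$se, dl$se, tolerance = 1e-12)
  expect_equal(mr0$tau2, dl$tau2, tolerance = 1e-12)

  # exact linear fit: y = 0.05 + 0.1 x, equal variances, tau2-hat = 0
  x <- seq(0, 1, length.out = 8)
  lin <- make_effects(0.05 + 0.1 * x, rep(0.2, 8))
  mr <- meta_regression(lin, data.frame(x = x))
  expect_equal(mr$tau2, 0)
  expect_equal(mr$coefficients$estimate, c(0.05, 0.1), tolerance = 1e-10)

  expect_error(meta_regression(lin, data.frame(x = x, x2 = 2 * x)),
               "collinear")
  expect_error(meta_regression(make_effects(c(0, 1), c(1, 1)),
                               data.frame(x = c(1, 2))),
               "more studies")
})

test_that("meta-regression on a binary moderator reproduces the subgroup test", {
  # with tau2-hat = 0 the coefficient z^2 equals Q_between exactly
  y <- c(0.10, 0.10, 0.10, 0.30, 0.30, 0.30) + c(1, -1, 0, 1, -1, 0) * 1e-4
  se <- rep(0.25, 6)
  g <- c(0, 0, 0, 1, 1, 1)
  eff <- make_effects(y, se)
  mr <- meta_regression(eff, data.frame(g = g))
  expect_equal(mr$tau2, 0)
  wi <- 1 / se^2
  mu_all <- sum(wi * y) / sum(wi)
  qb <- sum(vapply(unique(g), function(gg) {
    idx <- g == gg
    mu_g <- sum(wi[idx] * y[idx]) / sum(wi[idx])
    sum(wi[idx]) * (mu_g - mu_all)^2
  }, 0))
  z2 <- mr$coefficients$z[2]^2
  expect_equal(z2, qb, tolerance = 0.05 * qb)
})

test_that("subtype strata pool against the parent study's controls", {
  parent <- geno_row("s1", c(300, 500, 200), c(250, 500, 250))
  erp <- geno_row("s1", c(220, 330, 120), c(NA, NA, NA), stratum = "ERpos")
  ern <- geno_row("s1", c(80, 170, 80), c(NA, NA, NA), stratum = "ERneg")
  erp$n_control <- NA; ern$n_control <- NA
  tab <- as_study_table(rbind(parent, erp, ern))

  sc <- subtype_contrast(tab, stratum_pair = c("ERpos", "ERneg"))
  # both strata share the full parent control margin (allele counts)
  expect_equal(sc$effects$ERpos$c, 2 * 250 + 500)
  expect_equal(sc$effects$ERneg$c, 2 * 250 + 500)
  expect_equal(sc$effects$ERpos$a, 2 * 220 + 330)
  expect_equal(sc$k, 1)
  # z statistic consistent with the pooled difference
  d <- sc$pooled$ERpos$log_or - sc$pooled$ERneg$log_or
  expect_equal(sc$z, d / sqrt(sc$pooled$ERpos$se^2 + sc$pooled$ERneg$se^2),
               tolerance = 1e-12)

  expect_error(subtype_contrast(tab, stratum_pair = c("PRpos", "PRneg")),
               "no study carries both strata")
})
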