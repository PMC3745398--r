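test_that("inverse-variance pooling reproduces hand-computed values", {
  single <- pool_inverse_variance(make_effects(0.3, 0.15))
  expect_equal(single$log_or, 0.3)
  expect_equal(single$se, 0.15)
  expect_equal(single$q, 0)
  expect_equal(single$k, 1)

  # equal weights 100: pooled 0.1, Q = 2
  two <- pool_inverse_variance(make_effects(c(0, 0.2), c(0.1, 0.1)))
  expect_equal(two$log_or, 0.1, tolerance = 1e-12)
  expect_equal(two$q, 2, tolerance = 1e-12)
  expect_equal(two$se, 1 / sqrt(200), tolerance = 1e-12)

  trip <- pool_inverse_variance(make_effects(rep(0.1, 3), rep(0.2, 3)))
  expect_equal(trip$log_or, 0.1, tolerance = 1e-12)
  expect_equal(trip$se, 0.11547, tolerance = 1e-4)
  expect_equal(trip$q, 0, tolerance = 1e-12)

  expect_error(pool_inverse_variance(make_effects(numeric(0), numeric(0))),
               "no effects")
})

test_that("DerSimonian-Laird pooling matches its moment definition", {
  # Q = 2, C = 200 - 100 = 100 -> tau2 = 0.01; w* = 50 each
  dl <- pool_dersimonian_laird(make_effects(c(0, 0.2), c(0.1, 0.1)))
  expect_equal(dl$tau2, 0.01, tolerance = 1e-12)
  expect_equal(dl$log_or, 0.1, tolerance = 1e-12)
  expect_equal(dl$se, 0.1, tolerance = 1e-12)

  # homogeneous set truncates tau2 to 0 and reproduces the fixed effect
  hom <- make_effects(c(0.10, 0.11, 0.105), c(0.2, 0.25, 0.3))
  dl0 <- pool_dersimonian_laird(hom)
  iv <- pool_inverse_variance(hom)
  expect_equal(dl0$tau2, 0)
  expect_equal(dl0$log_or, iv$log_or, tolerance = 1e-14)
  expect_equal(dl0$se, iv$se, tolerance = 1e-14)

  # single study degrades to itself
  one <- pool_dersimonian_laird(make_effects(0.4, 0.2))
  expect_equal(one$log_or, 0.4)
  expect_equal(one$tau2, 0)
})

test_that("Mantel-Haenszel pooling matches hand-computed MH sums", {
  t1 <- contrast_table(10, 10, 10, 10)
  expect_equal(pool_mantel_haenszel(list(t1))$or_, 1, tolerance = 1e-12)

  t2 <- contrast_table(20, 10, 10, 20)
  mh <- pool_mantel_haenszel(list(t1, t2))
  expect_equal(mh$or_, (2.5 + 400 / 60) / (2.5 + 100 / 60), tolerance = 1e-12)
  expect_equal(round(mh$or_, 1), 2.2)

  # consensus: every table with identical OR pools to that OR
  set.seed(41)
  theta <- 1.7
  tabs <- lapply(1:6, function(i) {
    b <- sample(20:200, 1); c_ <- sample(20:200, 1); d <- sample(20:200, 1)
    a <- theta * b * c_ / d
    contrast_table(a, b, c_, d)
  })
  expect_equal(pool_mantel_haenszel(tabs)$or_, theta, tolerance = 1e-12)

  expect_error(pool_mantel_haenszel(list(contrast_table(5, 0, 0, 5))),
               "non-estimable")
})

test_that("heterogeneity statistics follow their definitions", {
  het <- heterogeneity(make_effects(c(0, 0.2), c(0.1, 0.1)))
  expect_equal(het$q, 2, tolerance = 1e-12)
  expect_equal(het$i2, 0.5, tolerance = 1e-12)

  same <- heterogeneity(make_effects(rep(0.3, 4), rep(0.1, 4)))
  expect_equal(same$q, 0)
  expect_equal(same$i2, 0)
  expect_equal(same$p_q, 1)

  # truncation: Q below its df gives I2 = 0
  low <- heterogeneity(make_effects(c(0.1, 0.129), c(0.2, 0.2)))
  expect_lt(low$q, 1)
  expect_equal(low$i2, 0)

  expect_error(heterogeneity(make_effects(0.1, 0.2)), "at least 2")
})

test_that("pooling agrees with metafor on the shipped reconstruction", {
  eff <- study_effects(table1(), "allele")
  dl <- pool_dersimonian_laird(eff)
  iv <- pool_inverse_variance(eff)
  mh <- pool_mantel_haenszel(eff)

  ref <- metafor::rma(yi = eff$log_or, vi = eff$se^2, method = "DL")
  expect_equal(dl$log_or, unname(coef(ref)), tolerance = 1e-10)
  expect_equal(dl$se, ref$se, tolerance = 1e-10)
  expect_equal(dl$tau2, ref$tau2, tolerance = 1e-10)
  expect_equal(dl$q, ref$QE, tolerance = 1e-10)
  expect_equal(dl$i2, ref$I2 / 100, tolerance = 1e-6)

  fe <- metafor::rma(yi = eff$log_or, vi = eff$se^2, method = "FE")
  expect_equal(iv$log_or, unname(coef(fe)), tolerance = 1e-10)
  expect_equal(iv$se, fe$se, tolerance = 1e-10)

  mh_ref <- metafor::rma.mh(ai = eff$a, bi = eff$b, ci = eff$c, di = eff$d,
                            measure = "OR", correct = FALSE)
  expect_equal(mh$log_or, unname(coef(mh_ref)), tolerance = 1e-10)
  expect_equal(mh$se, mh_ref$se, tolerance = 1e-10)
})

test_that("pooled estimates respect ordering and dispersion invariants", {
  set.seed(42)
  for (i in 1:15) {
    k <- sample(3:20, 1)
    eff <- make_effects(rnorm(k, 0.1, 0.3), runif(k, 0.05, 0.5))
    iv <- pool_inverse_variance(eff)
    dl <- pool_dersimonian_laird(eff)
    expect_gte(iv$log_or, min(eff$log_or))
    expect_lte(iv$log_or, max(eff$log_or))
    expect_gte(dl$log_or, min(eff$log_or))
    expect_lte(dl$log_or, max(eff$log_or))
    expect_gte(dl$se, iv$se)   # tau2 >= 0 always widens the CI
  }

  # large-sample equivalence of MH and IV on homogeneous tables
  set.seed(43)
  for (i in 1:5) {
    tab <- simulate_meta(simulation_config(k = 12, tau2 = 0,
                                           n_case_range = c(4000, 4000),
                                           n_control_range = c(4000, 4000),
                                           seed = 100 + i))
    eff <- study_effects(tab, "allele")
    stopifnot(all(c(eff$a, eff$b, eff$c, eff$d) >= 50))
    mh <- pool_mantel_haenszel(eff)
    iv <- pool_inverse_variance(eff)
    expect_equal(mh$or_, iv$or_, tolerance = 0.01)
  }
})
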