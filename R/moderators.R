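#' Subgroup analysis with between-subgroup heterogeneity
#'
#' Pools study effects within each level of a study-level moderator
#' (ethnic group, study design, ...) and tests heterogeneity *between*
#' subgroups by the fixed-effect Q decomposition: the total
#' inverse-variance Q splits exactly into the sum of within-group Qs plus
#' `Q_between = sum_g W_g (theta_g - theta_overall)^2`, where `W_g` is
#' the summed fixed-effect weight of group `g` and the `theta`s are
#' fixed-effect estimates. `Q_between` is referred to chi-square with
#' `G - 1` df. Headline per-group estimates use `method` (DL random
#' effects by default), while the decomposition itself is always computed
#' on fixed-effect estimates so the identity
#' `Q_total = sum Q_within + Q_between` holds exactly.
#'
#' @param table a `study_table`.
#' @param model genetic model passed to [study_effects()].
#' @param method per-group headline pooling method: `"DL_random"`,
#'   `"IV_fixed"` or `"MH_fixed"`.
#' @param group_by name of the grouping column (e.g. `"ethnic_group"`,
#'   `"design"`).
#' @return object of class `subgroup_report`: `group_by`, `groups`
#'   (named list of `pooled_result`), `overall` (pooled over all
#'   studies), `q_between`, `df_between`, `p_between`, `q_within`
#'   (named), `q_total`.
#' @export
subgroup_analysis <- function(table, model = "allele", method = "DL_random",
                              group_by = "ethnic_group") {
  method <- match.arg(method, POOL_METHODS)
  effects <- study_effects(table, model)
  if (nrow(effects) == 0) stop_domain("no usable effects")
  if (!group_by %in% names(effects))
    stop_domain("unknown grouping variable: ", group_by)
  g <- as.character(effects[[group_by]])
  keep <- !is.na(g)
  effects <- effects[keep, , drop = FALSE]; g <- g[keep]
  pool_with <- function(e) switch(method,
    DL_random = pool_dersimonian_laird(e),
    IV_fixed = pool_inverse_variance(e),
    MH_fixed = pool_mantel_haenszel(e))
  groups <- lapply(split(effects, g), pool_with)
  # fixed-effect decomposition
  wi <- 1 / effects$se^2
  mu_all <- sum(wi * effects$log_or) / sum(wi)
  q_total <- sum(wi * (effects$log_or - mu_all)^2)
  by_g <- split(seq_along(g), g)
  q_within <- vapply(by_g, function(idx) {
    mu_g <- sum(wi[idx] * effects$log_or[idx]) / sum(wi[idx])
    sum(wi[idx] * (effects$log_or[idx] - mu_g)^2)
  }, 0)
  q_between <- vapply(by_g, function(idx) {
    mu_g <- sum(wi[idx] * effects$log_or[idx]) / sum(wi[idx])
    sum(wi[idx]) * (mu_g - mu_all)^2
  }, 0)
  q_between <- sum(q_between)
  G <- length(by_g)
  structure(list(
    group_by = group_by, model = model, method = method,
    groups = groups, overall = pool_with(effects),
    q_between = q_between, df_between = G - 1L,
    p_between = if (G >= 2)
      stats::pchisq(q_between, G - 1L, lower.tail = FALSE) else NA_real_,
    q_within = q_within, q_total = q_total),
    class = "subgroup_report")
}

#' @export
print.subgroup_report <- function(x, ...) {
  cat(sprintf("Subgroup analysis by %s (%s model, %s)\n",
              x$group_by, x$model, x$method))
  for (nm in names(x$groups)) {
    g <- x$groups[[nm]]
    cat(sprintf("  %-12s k = %2d  OR = %.4f [%.4f, %.4f]  P(Q) = %.3g\n",
                nm, g$k, g$or_, g$ci_low, g$ci_high, g$p_q))
  }
  cat(sprintf("  Between-subgroup Q = %.3f (df = %d), p = %.3g\n",
              x$q_between, x$df_between, x$p_between))
  invisible(x)
}

#' Pool case-subtype strata against shared controls and test their difference
#'
#' For tumour-subtype questions (ER+ vs ER-, PR+ vs PR-, invasive vs
#' in situ) each stratum's cases are contrasted against the parent
#' study's full control group, each stratum is pooled across studies, and
#' the two pooled log ORs are compared with a normal z test. The two
#' strata share controls, so their estimates are positively correlated;
#' the test treats them as independent because the covariance is not
#' recoverable from study-level counts, making it mildly conservative.
#' This approximation is recorded in the returned object.
#'
#' @param table a `study_table` with stratum rows.
#' @param model genetic model (strata usually publish allele or genotype
#'   counts; RAF-only strata support `"allele"`).
#' @param stratum_pair character pair, e.g. `c("ERpos", "ERneg")`.
#' @param method pooling method for each stratum.
#' @return object of class `subtype_contrast`: per-stratum
#'   `pooled_result`s, `diff` (log OR difference), `se_diff`, `z`, `p`,
#'   `k` (studies contributing both strata), `independence_assumed`.
#' @export
subtype_contrast <- function(table, model = "allele",
                             stratum_pair = c("ERpos", "ERneg"),
                             method = "DL_random") {
  stopifnot(length(stratum_pair) == 2)
  method <- match.arg(method, POOL_METHODS)
  df <- as.data.frame(table)
  whole <- df[is.na(df$stratum), , drop = FALSE]
  strat <- df[!is.na(df$stratum) & df$stratum %in% stratum_pair, ,
              drop = FALSE]
  both <- intersect(strat$study_id[strat$stratum == stratum_pair[1]],
                    strat$study_id[strat$stratum == stratum_pair[2]])
  if (length(both) == 0)
    stop_domain("no study carries both strata: ",
                paste(stratum_pair, collapse = " vs "))
  one_stratum_effects <- function(label) {
    rows <- lapply(both, function(id) {
      s <- strat[strat$study_id == id & strat$stratum == label, ][1, ]
      p <- whole[whole$study_id == id, ][1, ]
      # stratum cases against the parent's controls
      s$ctrl_rr <- p$ctrl_rr; s$ctrl_rn <- p$ctrl_rn; s$ctrl_nn <- p$ctrl_nn
      s$raf_control <- p$raf_control; s$n_control <- p$n_control
      eff <- woolf_effect(build_contrast(s, model))
      data.frame(study_id = id, model = model, a = eff$a, b = eff$b,
                 c = eff$c, d = eff$d, or = eff$or_, ci_low = eff$ci_low,
                 ci_high = eff$ci_high, log_or = eff$log_or, se = eff$se,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  e1 <- one_stratum_effects(stratum_pair[1])
  e2 <- one_stratum_effects(stratum_pair[2])
  pool_with <- function(e) switch(method,
    DL_random = pool_dersimonian_laird(e),
    IV_fixed = pool_inverse_variance(e),
    MH_fixed = pool_mantel_haenszel(e))
  p1 <- pool_with(e1); p2 <- pool_with(e2)
  d <- p1$log_or - p2$log_or
  se_d <- sqrt(p1$se^2 + p2$se^2)
  structure(list(stratum_pair = stratum_pair, model = model,
                 method = method, k = length(both),
                 pooled = stats::setNames(list(p1, p2), stratum_pair),
                 effects = stats::setNames(list(e1, e2), stratum_pair),
                 diff = d, se_diff = se_d, z = d / se_d,
                 p = 2 * stats::pnorm(-abs(d / se_d)),
                 independence_assumed = TRUE),
            class = "subtype_contrast")
}

#' @export
print.subtype_contrast <- function(x, ...) {
  cat(sprintf("Subtype contrast %s vs %s (%s model, %s, k = %d)\n",
              x$stratum_pair[1], x$stratum_pair[2], x$model, x$method, x$k))
  for (nm in x$stratum_pair) {
    g <- x$pooled[[nm]]
    cat(sprintf("  %-9s OR = %.4f [%.4f, %.4f]\n", nm, g$or_, g$ci_low,
                g$ci_high))
  }
  cat(sprintf("  difference in log OR = %.4f (SE %.4f), z = %.3f, p = %.3g\n",
              x$diff, x$se_diff, x$z, x$p))
  cat("  (strata share controls; difference test assumes independence)\n")
  invisible(x)
}

#' Random-effects meta-regression of study effects on moderators
#'
#' Weighted least squares of the per-study log ORs on a design matrix of
#' study-level moderators, with a method-of-moments residual
#' between-study variance (the DerSimonian-Laird estimator generalized to
#' a design matrix): with fixed-effect weights `W = diag(1/v_i)` and hat
#' complement `P = W - W X (X'WX)^-1 X'W`, the residual Q is
#' `Q_E = y'Py` and `tau2 = max(0, (Q_E - (k - p)) / tr(P))`. Final
#' coefficients are WLS with weights `1/(v_i + tau2)`; tests are
#' z-based. With an intercept-only design this reduces exactly to
#' [pool_dersimonian_laird()].
#'
#' @param effects per-study effects (data.frame with `log_or`, `se`).
#' @param moderators data.frame of covariates, one row per effect
#'   (factors/characters are expanded to dummies via [stats::model.matrix()]),
#'   or `NULL` for intercept-only.
#' @return object of class `meta_regression`: `coefficients` data.frame
#'   (`term, estimate, se, z, p`), `tau2`, `qe` (residual Q), `k`,
#'   `p` (number of coefficients).
#' @export
meta_regression <- function(effects, moderators = NULL) {
  e <- effects_input(effects)
  k <- length(e$yi)
  if (is.null(moderators)) {
    X <- matrix(1, k, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stopifnot(is.data.frame(moderators), nrow(moderators) == k)
    if (anyNA(moderators))
      stop_domain("moderators contain missing values")
    X <- stats::model.matrix(~ ., data = moderators)
  }
  p <- ncol(X)
  if (k <= p)
    stop_domain("need more studies (", k, ") than coefficients (", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop_domain("rank-deficient design; collinear column(s): ",
                paste(bad, collapse = ", "))
  }
  wi <- 1 / e$vi
  W <- diag(wi, k)
  XtWX_inv <- solve(t(X) %*% W %*% X)
  Pmat <- W - W %*% X %*% XtWX_inv %*% t(X) %*% W
  qe <- drop(t(e$yi) %*% Pmat %*% e$yi)
  tau2 <- max(0, (qe - (k - p)) / sum(diag(Pmat)))
  ws <- 1 / (e$vi + tau2)
  Ws <- diag(ws, k)
  V <- solve(t(X) %*% Ws %*% X)
  beta <- drop(V %*% t(X) %*% Ws %*% e$yi)
  se <- sqrt(diag(V))
  z <- beta / se
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = beta,
                              se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
                              row.names = NULL, stringsAsFactors = FALSE),
    tau2 = tau2, qe = qe, k = k, p = p),
    class = "meta_regression")
}

#' @export
print.meta_regression <- function(x, ...) {
  cat(sprintf("Meta-regression (k = %d, residual tau2 = %.5f, QE = %.3f)\n",
              x$k, x$tau2, x$qe))
  print(x$coefficients, digits = 4)
  invisible(x)
}
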