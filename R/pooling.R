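POOL_METHODS <- c("DL_random", "IV_fixed", "MH_fixed")

new_pooled_result <- function(model, method, k, log_or, se, q, df, tau2,
                              weights = NULL) {
  z <- log_or / se
  p_q <- if (df >= 1) stats::pchisq(q, df, lower.tail = FALSE) else NA_real_
  structure(list(
    model = model, method = method, k = k,
    log_or = log_or, se = se, or_ = exp(log_or),
    ci_low = exp(log_or - Z975 * se), ci_high = exp(log_or + Z975 * se),
    z = z, p_z = 2 * stats::pnorm(-abs(z)),
    q = q, df = df, p_q = p_q,
    i2 = if (q > 0) max(0, (q - df) / q) else 0,
    tau2 = tau2, weights = weights),
    class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Pooled %s (%s, k = %d)\n", x$model, x$method, x$k))
  cat(sprintf("  OR = %.4f [%.4f, %.4f], Z = %.3f, P(Z) = %.3g\n",
              x$or_, x$ci_low, x$ci_high, x$z, x$p_z))
  cat(sprintf("  Q = %.3f (df = %d), P(Q) = %.3g, I2 = %.1f%%, tau2 = %.5f\n",
              x$q, x$df, x$p_q, 100 * x$i2, x$tau2))
  invisible(x)
}

# Accept either an effects data.frame (log_or, se columns) or a list of
# effect_estimate objects; returns list(yi, vi, model, ids).
effects_input <- function(effects) {
  if (is.data.frame(effects)) {
    stopifnot(all(c("log_or", "se") %in% names(effects)))
    list(yi = effects$log_or, vi = effects$se^2,
         model = if (nrow(effects) > 0 && "model" %in% names(effects))
                   effects$model[1] else NA_character_,
         ids = effects$study_id %||% rep(NA_character_, nrow(effects)))
  } else if (is.list(effects) && all(vapply(effects, inherits, TRUE,
                                            "effect_estimate"))) {
    list(yi = vapply(effects, `[[`, 0, "log_or"),
         vi = vapply(effects, `[[`, 0, "se")^2,
         model = if (length(effects) > 0) effects[[1]]$model else NA_character_,
         ids = vapply(effects, `[[`, "", "study_id"))
  } else stop_domain("effects must be a data.frame or list of effect estimates")
}

iv_core <- function(yi, vi) {
  wi <- 1 / vi
  mu <- sum(wi * yi) / sum(wi)
  list(wi = wi, mu = mu, se = 1 / sqrt(sum(wi)),
       q = sum(wi * (yi - mu)^2))
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights each study by the reciprocal of its sampling variance:
#' `w_i = 1/se_i^2`, pooled `log OR = sum(w y) / sum(w)`,
#' `SE = 1/sqrt(sum(w))`, Wald `Z` with two-sided normal p, and Cochran's
#' `Q = sum w (y - ybar)^2` on `k - 1` df.
#'
#' @param effects per-study effects: data.frame from [study_effects()]
#'   (columns `log_or`, `se`) or a list of [woolf_effect()] results.
#' @return a `pooled_result`.
#' @export
pool_inverse_variance <- function(effects) {
  e <- effects_input(effects)
  k <- length(e$yi)
  if (k < 1) stop_domain("no effects to pool")
  if (any(e$vi <= 0)) stop_domain("all standard errors must be positive")
  f <- iv_core(e$yi, e$vi)
  new_pooled_result(e$model, "IV_fixed", k, f$mu, f$se, f$q, k - 1L,
                    tau2 = 0, weights = f$wi)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))` with
#' fixed-effect weights `w_i = 1/v_i`, then re-pooling with
#' `w*_i = 1/(v_i + tau2)`. Homogeneous sets (`Q <= k - 1`) truncate to
#' `tau2 = 0` and reproduce the fixed-effect result exactly; a single
#' study degrades to its own estimate. `Q`, `P(Q)` and `I2` are reported
#' from the fixed-effect weights, as is conventional.
#'
#' @inheritParams pool_inverse_variance
#' @return a `pooled_result`.
#' @examples
#' eff <- data.frame(study_id = c("s1", "s2"), log_or = c(0, 0.2),
#'                   se = c(0.1, 0.1))
#' pool_dersimonian_laird(eff)   # tau2 = 0.01, pooled log OR = 0.1
#' @export
pool_dersimonian_laird <- function(effects) {
  e <- effects_input(effects)
  k <- length(e$yi)
  if (k < 1) stop_domain("no effects to pool")
  if (any(e$vi <= 0)) stop_domain("all standard errors must be positive")
  f <- iv_core(e$yi, e$vi)
  tau2 <- 0
  if (k >= 2) {
    C <- sum(f$wi) - sum(f$wi^2) / sum(f$wi)
    tau2 <- max(0, (f$q - (k - 1)) / C)
  }
  ws <- 1 / (e$vi + tau2)
  mu <- sum(ws * e$yi) / sum(ws)
  new_pooled_result(e$model, "DL_random", k, mu, 1 / sqrt(sum(ws)),
                    f$q, k - 1L, tau2 = tau2, weights = ws)
}

#' Mantel-Haenszel fixed-effect pooling of 2x2 tables
#'
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` over the raw
#' (uncorrected) tables, with the Robins-Breslow-Greenland variance for
#' `log OR_MH`. Cochran's `Q` is computed on the per-table Woolf effects,
#' so heterogeneity is reported on the same scale as the other methods.
#'
#' @param tables list of [contrast_table()] objects, or a data.frame with
#'   columns `a, b, c, d` (e.g. from [study_effects()]).
#' @return a `pooled_result`.
#' @export
pool_mantel_haenszel <- function(tables) {
  if (is.data.frame(tables)) {
    stopifnot(all(c("a", "b", "c", "d") %in% names(tables)))
    A <- tables$a; B <- tables$b; C_ <- tables$c; D <- tables$d
    model <- if (nrow(tables) > 0 && "model" %in% names(tables))
      tables$model[1] else NA_character_
  } else {
    stopifnot(all(vapply(tables, inherits, TRUE, "contrast_table")))
    A <- vapply(tables, `[[`, 0, "a"); B <- vapply(tables, `[[`, 0, "b")
    C_ <- vapply(tables, `[[`, 0, "c"); D <- vapply(tables, `[[`, 0, "d")
    model <- if (length(tables) > 0) tables[[1]]$model else NA_character_
  }
  k <- length(A)
  if (k < 1) stop_domain("no tables to pool")
  n <- A + B + C_ + D
  if (any(n <= 0)) stop_domain("empty stratum table")
  R <- A * D / n; S <- B * C_ / n
  if (sum(S) == 0) stop_domain("MH odds ratio non-estimable: sum(bc/n) = 0")
  or_mh <- sum(R) / sum(S)
  # Robins-Breslow-Greenland variance of log OR_MH
  P <- (A + D) / n; Q_ <- (B + C_) / n
  var_mh <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q_ * R) / (2 * sum(R) * sum(S)) +
    sum(Q_ * S) / (2 * sum(S)^2)
  # heterogeneity on the Woolf per-table effects
  effs <- lapply(seq_len(k), function(i)
    woolf_effect(contrast_table(A[i], B[i], C_[i], D[i], model = "allele")))
  ok <- vapply(effs, `[[`, TRUE, "estimable")
  q <- if (sum(ok) >= 2) {
    yi <- vapply(effs[ok], `[[`, 0, "log_or")
    vi <- vapply(effs[ok], `[[`, 0, "se")^2
    iv_core(yi, vi)$q
  } else 0
  new_pooled_result(model, "MH_fixed", k, log(or_mh), sqrt(var_mh),
                    q, k - 1L, tau2 = 0)
}

#' Cochran's Q heterogeneity test and I-squared
#'
#' `Q` is the fixed-effect weighted sum of squared deviations of the
#' study effects around the pooled effect, referred to a chi-square with
#' `k - 1` df; `I2 = max(0, (Q - df)/Q)` is the fraction of total
#' variation attributed to between-study heterogeneity.
#'
#' @inheritParams pool_inverse_variance
#' @return list with `q`, `df`, `p_q`, `i2`.
#' @export
heterogeneity <- function(effects) {
  e <- effects_input(effects)
  k <- length(e$yi)
  if (k < 2) stop_domain("heterogeneity requires at least 2 studies")
  f <- iv_core(e$yi, e$vi)
  list(q = f$q, df = k - 1L,
       p_q = stats::pchisq(f$q, k - 1L, lower.tail = FALSE),
       i2 = if (f$q > 0) max(0, (f$q - (k - 1)) / f$q) else 0)
}
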