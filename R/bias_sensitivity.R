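#' Egger regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `y_i / se_i` on
#' precision `1 / se_i`; under no small-study effect the points fall on a
#' line through the origin, so a non-zero intercept signals asymmetry.
#' The intercept is tested with a t statistic on `k - 2` df, two-sided.
#' A perfectly collinear configuration (zero residual variance, which
#' arises in constructed examples) is reported as intercept exactly on
#' its fitted value with `p = 1` when that value is 0.
#'
#' @param effects per-study effects (data.frame with `log_or`, `se`), at
#'   least 3 studies.
#' @return list with `intercept`, `se`, `t`, `df`, `p`, `slope`.
#' @export
egger_test <- function(effects) {
  e <- effects_input(effects)
  k <- length(e$yi)
  if (k < 3) stop_domain("Egger's test needs at least 3 studies")
  sei <- sqrt(e$vi)
  fit <- stats::lm(I(e$yi / sei) ~ I(1 / sei))
  # summary.lm warns on an exactly collinear (zero-residual) construction,
  # which the branch below handles explicitly
  cf <- suppressWarnings(summary(fit))$coefficients
  if (nrow(cf) < 2 || anyNA(cf[, 2]))
    stop_domain("Egger regression degenerate (equal precisions?)")
  est <- cf[1, 1]; se <- cf[1, 2]
  if (se < 1e-10) {              # exact fit: no sampling variability left
    t <- 0; p <- if (abs(est) < 1e-8) 1 else 0
    est <- if (abs(est) < 1e-8) 0 else est
  } else {
    t <- est / se
    p <- 2 * stats::pt(-abs(t), df = k - 2)
  }
  list(intercept = est, se = se, t = t, df = k - 2L, p = p,
       slope = cf[2, 1])
}

# Kendall rank correlation by brute-force pair counting with tau-b style
# tie correction in the variance; k here is small (number of studies).
kendall_tau <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 2)
  C <- 0; D <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
    }
  }
  T_ <- C - D
  tie_counts <- function(v) { t <- table(v); t[t > 1] }
  tx <- as.numeric(tie_counts(x)); ty <- as.numeric(tie_counts(y))
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5)); vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  var_T <- (v0 - vt - vu) / 18
  if (n > 2)
    var_T <- var_T +
      sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
        (9 * n * (n - 1) * (n - 2))
  var_T <- var_T + sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  list(tau = T_ / (n * (n - 1) / 2), T_ = T_, var_T = var_T,
       concordant = C, discordant = D)
}

#' Begg-Mazumdar rank correlation test for publication bias
#'
#' Kendall rank correlation between the standardized deviates
#' `u_i = (y_i - ybar_fixed) / sqrt(v_i - v_pooled)` and the sampling
#' variances `v_i`, where `ybar_fixed` and `v_pooled` are the
#' fixed-effect pooled estimate and its variance. The test statistic
#' `T = concordant - discordant` is referred to its null variance with
#' tie correction (ties are routine when variances are reconstructed from
#' rounded tables) and a continuity correction. Numerically non-positive
#' `v_i - v_pooled` (the smallest study dominating) is clamped to a small
#' positive value with a warning.
#'
#' @inheritParams egger_test
#' @return list with `tau`, `z`, `p`, `concordant`, `discordant`.
#' @export
begg_test <- function(effects) {
  e <- effects_input(effects)
  k <- length(e$yi)
  if (k < 3) stop_domain("Begg's test needs at least 3 studies")
  f <- iv_core(e$yi, e$vi)
  vstar <- e$vi - 1 / sum(f$wi)
  if (any(vstar <= 0)) {
    warning("clamping non-positive variance difference in Begg deviates",
            call. = FALSE)
    vstar[vstar <= 0] <- .Machine$double.eps * max(e$vi)
  }
  u <- (e$yi - f$mu) / sqrt(vstar)
  kt <- kendall_tau(u, e$vi)
  z <- if (kt$var_T > 0) (kt$T_ - sign(kt$T_)) / sqrt(kt$var_T) else 0
  list(tau = kt$tau, z = z, p = 2 * stats::pnorm(-abs(z)),
       concordant = kt$concordant, discordant = kt$discordant)
}

#' Combined publication-bias report
#'
#' Runs [egger_test()], [begg_test()] and [funnel_data()] on one effect
#' set and bundles them for export.
#'
#' @inheritParams egger_test
#' @return object of class `bias_report` with elements `egger`, `begg`,
#'   `funnel`, `k`.
#' @export
bias_report <- function(effects) {
  structure(list(egger = egger_test(effects), begg = begg_test(effects),
                 funnel = funnel_data(effects),
                 k = nrow(funnel_data(effects))),
            class = "bias_report")
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("Publication-bias diagnostics (k = %d)\n", x$k))
  cat(sprintf("  Egger: intercept = %.4f (SE %.4f), t = %.3f, p = %.3g\n",
              x$egger$intercept, x$egger$se, x$egger$t, x$egger$p))
  cat(sprintf("  Begg:  tau = %.4f, z = %.3f, p = %.3g\n",
              x$begg$tau, x$begg$z, x$begg$p))
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' One point per study: `(log_or, se)`. By funnel-plot convention the
#' standard-error axis is drawn inverted (largest studies on top); that
#' convention is recorded in the `"se_axis"` attribute rather than baked
#' into the data.
#'
#' @inheritParams egger_test
#' @return data.frame `study_id, log_or, se` with attribute
#'   `se_axis = "reversed"`.
#' @export
funnel_data <- function(effects) {
  e <- effects_input(effects)
  if (length(e$yi) < 1) stop_domain("funnel data needs at least 1 study")
  out <- data.frame(study_id = e$ids, log_or = e$yi, se = sqrt(e$vi),
                    stringsAsFactors = FALSE)
  attr(out, "se_axis") <- "reversed"
  out
}

#' Leave-one-out influence analysis
#'
#' Re-pools the meta-analysis `k` times, each time deleting one study,
#' to measure the influence of each dataset on the pooled OR. Flags
#' whether any omission moves the pooled estimate across the OR = 1
#' significance boundary (i.e. changes whether the 95% CI excludes 1).
#'
#' @param table a `study_table`.
#' @param model genetic model.
#' @param method pooling method (`"DL_random"`, `"IV_fixed"`,
#'   `"MH_fixed"`).
#' @return object of class `influence_report`: `results` data.frame
#'   (`omitted, k, or, ci_low, ci_high, tau2`), `or_min`, `or_max`,
#'   `full` (the all-studies `pooled_result`), `crosses_null`.
#' @export
influence_analysis <- function(table, model = "allele", method = "DL_random") {
  method <- match.arg(method, POOL_METHODS)
  effects <- study_effects(table, model)
  k <- nrow(effects)
  if (k < 2) stop_domain("influence analysis needs at least 2 studies")
  pool_with <- function(e) switch(method,
    DL_random = pool_dersimonian_laird(e),
    IV_fixed = pool_inverse_variance(e),
    MH_fixed = pool_mantel_haenszel(e))
  full <- pool_with(effects)
  rows <- lapply(seq_len(k), function(i) {
    p <- pool_with(effects[-i, , drop = FALSE])
    data.frame(omitted = effects$study_id[i], k = p$k, or = p$or_,
               ci_low = p$ci_low, ci_high = p$ci_high, tau2 = p$tau2,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  sig <- function(lo, hi) lo > 1 || hi < 1
  structure(list(results = res, or_min = min(res$or), or_max = max(res$or),
                 full = full,
                 crosses_null = any(vapply(seq_len(k), function(i)
                   sig(res$ci_low[i], res$ci_high[i]) !=
                     sig(full$ci_low, full$ci_high), TRUE))),
            class = "influence_report")
}

#' @export
print.influence_report <- function(x, ...) {
  cat(sprintf("Leave-one-out influence (%s, %s model, k = %d)\n",
              x$full$method, x$full$model, nrow(x$results)))
  cat(sprintf("  full OR = %.4f [%.4f, %.4f]; omission range [%.4f, %.4f]\n",
              x$full$or_, x$full$ci_low, x$full$ci_high, x$or_min, x$or_max))
  cat(if (x$crosses_null)
    "  WARNING: at least one omission crosses the OR = 1 boundary\n"
    else "  no omission crosses the OR = 1 significance boundary\n")
  invisible(x)
}
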