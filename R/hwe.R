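#' Hardy-Weinberg equilibrium chi-square test for a genotype triple
#'
#' Pearson goodness-of-fit test of observed genotype counts
#' `(rr, rn, nn)` against the Hardy-Weinberg expectations
#' `n p^2, 2 n p (1 - p), n (1 - p)^2` at the sample allele frequency
#' `p = (2 rr + rn) / (2 n)`, with 1 degree of freedom (one estimated
#' parameter). Deviation from HWE in control genotypes is the standard
#' screen for genotyping error in association studies.
#'
#' Monomorphic samples (`p` of 0 or 1) carry no information about HWE:
#' they return `chi2 = 0`, `p_value = 1` and are flagged.
#'
#' @param genotypes numeric triple `(rr, rn, nn)` of non-negative counts.
#' @param alpha significance level deciding `passes` (default 0.05).
#' @return object of class `hwe_result`: `chi2`, `df` (1), `p_value`,
#'   `expected` triple, `p_hat`, `monomorphic`, `passes`.
#' @examples
#' hwe_chi2(c(30, 40, 30))   # chi2 = 4, p ~ 0.0455
#' @export
hwe_chi2 <- function(genotypes, alpha = 0.05) {
  g <- as.numeric(genotypes)
  if (length(g) != 3 || anyNA(g) || any(g < 0))
    stop_domain("genotypes must be a non-negative triple (rr, rn, nn)")
  n <- sum(g)
  if (n == 0) stop_domain("empty genotype sample")
  p_hat <- (2 * g[1] + g[2]) / (2 * n)
  monomorphic <- p_hat %in% c(0, 1)
  if (monomorphic) {
    expected <- genotype_table_from_hwe(p_hat, n)
    chi2 <- 0; p_value <- 1
  } else {
    expected <- genotype_table_from_hwe(p_hat, n)
    chi2 <- sum((g - expected)^2 / expected)
    p_value <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(list(chi2 = chi2, df = 1L, p_value = p_value,
                 expected = expected, p_hat = p_hat,
                 monomorphic = monomorphic,
                 passes = p_value >= alpha),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f (df = 1), p = %.4g%s -> %s\n",
              x$chi2, x$p_value,
              if (x$monomorphic) " [monomorphic]" else "",
              if (x$passes) "consistent with HWE" else "deviates from HWE"))
  invisible(x)
}

#' Filter a study table by HWE in controls
#'
#' Applies the inclusion rule that control genotype distributions must be
#' consistent with Hardy-Weinberg equilibrium: whole-study rows with
#' control genotype counts are tested with [hwe_chi2()] and excluded
#' (together with their stratum rows) when `p < alpha`. Rows publishing
#' only RAF + N cannot be tested and are retained with a
#' `"not_testable"` flag and a warning, since rejecting them would discard
#' studies on missing information rather than evidence.
#'
#' @param table a `study_table`.
#' @param alpha HWE significance level (default 0.05).
#' @return list with `table` (retained rows, order preserved) and `log`
#'   (data.frame `study_id, hwe_chi2, hwe_p, action` with action
#'   `excluded` or `not_testable`; studies passing the test do not
#'   appear, so an all-consistent table yields an empty log).
#' @export
filter_studies_by_hwe <- function(table, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  df <- as.data.frame(table)
  whole <- which(is.na(df$stratum))
  log <- data.frame(study_id = character(0), hwe_chi2 = numeric(0),
                    hwe_p = numeric(0), action = character(0),
                    stringsAsFactors = FALSE)
  drop_ids <- character(0)
  for (i in whole) {
    gt <- as.numeric(df[i, c("ctrl_rr", "ctrl_rn", "ctrl_nn")])
    if (anyNA(gt)) {
      log <- rbind(log, data.frame(study_id = df$study_id[i],
                                   hwe_chi2 = NA_real_, hwe_p = NA_real_,
                                   action = "not_testable"))
      next
    }
    res <- hwe_chi2(gt, alpha = alpha)
    if (!res$passes) {
      drop_ids <- c(drop_ids, df$study_id[i])
      log <- rbind(log, data.frame(study_id = df$study_id[i],
                                   hwe_chi2 = res$chi2, hwe_p = res$p_value,
                                   action = "excluded"))
    }
  }
  if (any(log$action == "not_testable"))
    warning("HWE not testable (RAF-only rows) for: ",
            paste(log$study_id[log$action == "not_testable"], collapse = ", "),
            call. = FALSE)
  keep <- !(df$study_id %in% drop_ids)
  out <- new_study_table(df[keep, , drop = FALSE],
                         provenance = attr(table, "provenance"))
  list(table = out, log = log)
}
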