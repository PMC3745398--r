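GENETIC_MODELS <- c("allele", "dominant", "recessive", "heterozygous",
                    "homozygous")

#' 2x2 contrast table for one study under one genetic model
#'
#' Cells follow the epidemiological convention: `a` exposed cases,
#' `b` unexposed cases, `c` exposed controls, `d` unexposed controls,
#' where "exposed" means carrying the risk allele/genotype defined by the
#' model. For the allele model the margins are allele counts (2 per
#' subject); for genotype models they are subjects, with the co-dominant
#' (heterozygous, homozygous) contrasts dropping the excluded genotype
#' class from the denominators.
#'
#' @param a,b,c_,d non-negative counts.
#' @param model one of `"allele"`, `"dominant"`, `"recessive"`,
#'   `"heterozygous"`, `"homozygous"`.
#' @param study_id optional label carried through to effect estimates.
#' @return object of class `contrast_table`.
#' @export
contrast_table <- function(a, b, c_, d, model = "allele", study_id = NA_character_) {
  model <- match.arg(model, GENETIC_MODELS)
  cells <- c(a = a, b = b, c = c_, d = d)
  if (anyNA(cells) || any(cells < 0))
    stop_domain("contrast table cells must be non-negative counts")
  structure(list(study_id = study_id, model = model,
                 a = a, b = b, c = c_, d = d, corrected = FALSE),
            class = "contrast_table")
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(sprintf("Contrast table (%s model%s)%s\n", x$model,
              if (x$corrected) ", continuity-corrected" else "",
              if (is.na(x$study_id)) "" else paste0(" - ", x$study_id)))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("case", "control"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Build the 2x2 contrast table for a study under a genetic model
#'
#' With genotype triples `(rr, rn, nn)` for risk allele A:
#' * allele: A vs G allele counts, `a = 2 rr + rn`;
#' * dominant: carriers (AA + AG) vs GG;
#' * recessive: AA vs (AG + GG);
#' * heterozygous: AG vs GG (AA dropped);
#' * homozygous: AA vs GG (AG dropped).
#'
#' Studies publishing only RAF + N support the allele model alone, via
#' [allele_table_from_raf()]; requesting a genotype model on such a record
#' is an error that names the usable models.
#'
#' @param record one study row (a one-row `study_table` slice, list, or
#'   data.frame row) with the study-table fields.
#' @param model genetic model, see above.
#' @return a [contrast_table()].
#' @export
build_contrast <- function(record, model = "allele") {
  model <- match.arg(model, GENETIC_MODELS)
  rec <- as.list(as.data.frame(record))
  id <- rec$study_id %||% NA_character_
  gc <- c(rec$case_rr, rec$case_rn, rec$case_nn)
  gt <- c(rec$ctrl_rr, rec$ctrl_rn, rec$ctrl_nn)
  have_geno <- length(gc) == 3 && length(gt) == 3 && !anyNA(gc) && !anyNA(gt)
  if (!have_geno) {
    if (model != "allele")
      stop_domain("study ", id, " has no genotype counts; usable models: allele")
    tab <- allele_table_from_raf(rec$raf_case, rec$n_case,
                                 rec$raf_control, rec$n_control)
    tab$study_id <- id
    return(tab)
  }
  cells <- switch(model,
    allele       = c(2 * gc[1] + gc[2], 2 * gc[3] + gc[2],
                     2 * gt[1] + gt[2], 2 * gt[3] + gt[2]),
    dominant     = c(gc[1] + gc[2], gc[3], gt[1] + gt[2], gt[3]),
    recessive    = c(gc[1], gc[2] + gc[3], gt[1], gt[2] + gt[3]),
    heterozygous = c(gc[2], gc[3], gt[2], gt[3]),
    homozygous   = c(gc[1], gc[3], gt[1], gt[3]))
  contrast_table(cells[1], cells[2], cells[3], cells[4],
                 model = model, study_id = id)
}

#' Woolf log odds ratio for a 2x2 table
#'
#' The Woolf method: `log OR = ln(ad / bc)` with asymptotic standard
#' error `sqrt(1/a + 1/b + 1/c + 1/d)` and normal 95% CI on the log
#' scale. If any cell is zero, the Haldane-Anscombe continuity correction
#' adds 0.5 to all four cells first (`corrected` is set). Tables whose
#' odds ratio is undefined even in principle (an empty margin, e.g.
#' `a = c = 0`) are flagged non-estimable.
#'
#' @param table a [contrast_table()].
#' @return object of class `effect_estimate`: study_id, model, cells,
#'   `log_or`, `se`, `or_`, `ci_low`, `ci_high`, `corrected`, `estimable`.
#' @examples
#' woolf_effect(contrast_table(4774, 4066, 17365, 17365))
#' @export
woolf_effect <- function(table) {
  stopifnot(inherits(table, "contrast_table"))
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  estimable <- !((a == 0 && c_ == 0) || (b == 0 && d == 0) ||
                 (a + b == 0) || (c_ + d == 0))
  corrected <- FALSE
  if (estimable && any(c(a, b, c_, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  if (estimable) {
    log_or <- log(a * d / (b * c_))
    se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  } else {
    log_or <- NA_real_; se <- NA_real_
  }
  structure(list(study_id = table$study_id, model = table$model,
                 a = table$a, b = table$b, c = table$c, d = table$d,
                 log_or = log_or, se = se, or_ = exp(log_or),
                 ci_low = exp(log_or - Z975 * se),
                 ci_high = exp(log_or + Z975 * se),
                 corrected = corrected, estimable = estimable),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat("Non-estimable effect (", x$model, " model)\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("%s model OR = %.4f [%.4f, %.4f]  log OR = %.4f (SE %.4f)%s\n",
              x$model, x$or_, x$ci_low, x$ci_high, x$log_or, x$se,
              if (x$corrected) "  [continuity-corrected]" else ""))
  invisible(x)
}

#' Per-study effect estimates for a whole table
#'
#' Applies [build_contrast()] + [woolf_effect()] to every whole-study row
#' (stratum rows are handled by [subtype_contrast()]). Studies that cannot
#' support the requested model (RAF-only rows asked for a genotype model)
#' or whose table is non-estimable are dropped with a warning, so a mixed
#' table never aborts a model it can partially serve.
#'
#' @param table a `study_table`.
#' @param model genetic model.
#' @return data.frame, one row per usable study: `study_id, model, a, b,
#'   c, d, or, ci_low, ci_high, log_or, se, corrected` (forest-plot /
#'   export layout), plus moderator columns `ethnic_group, design,
#'   control_source, genotyping_method, year, n_case, n_control`.
#' @export
study_effects <- function(table, model = "allele") {
  model <- match.arg(model, GENETIC_MODELS)
  df <- as.data.frame(table)
  df <- df[is.na(df$stratum), , drop = FALSE]
  rows <- list(); skipped <- character(0)
  for (i in seq_len(nrow(df))) {
    eff <- tryCatch(woolf_effect(build_contrast(df[i, ], model)),
                    error = function(e) NULL)
    if (is.null(eff) || !eff$estimable) {
      skipped <- c(skipped, df$study_id[i])
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      study_id = eff$study_id, model = model,
      a = eff$a, b = eff$b, c = eff$c, d = eff$d,
      or = eff$or_, ci_low = eff$ci_low, ci_high = eff$ci_high,
      log_or = eff$log_or, se = eff$se, corrected = eff$corrected,
      ethnic_group = df$ethnic_group[i] %||% NA_character_,
      design = df$design[i], control_source = df$control_source[i],
      genotyping_method = df$genotyping_method[i], year = df$year[i],
      n_case = df$n_case[i], n_control = df$n_control[i],
      stringsAsFactors = FALSE)
  }
  if (length(skipped) > 0)
    warning("studies skipped for model '", model, "': ",
            paste(skipped, collapse = ", "), call. = FALSE)
  if (length(rows) == 0) {
    out <- data.frame(study_id = character(0))
  } else {
    out <- do.call(rbind, rows)
  }
  out
}
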