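#' Pipeline run configuration
#'
#' Collects the analysis choices for one end-to-end run: which genetic
#' models and pooling methods to compute, which moderators to stratify
#' on, the HWE inclusion threshold, and where to write the report bundle.
#'
#' @param input path to a study-table TSV, or a `study_table` object.
#' @param models subset of the five genetic models.
#' @param methods subset of `c("DL_random", "MH_fixed", "IV_fixed")`;
#'   the first is the headline method used for subgroup/bias/influence.
#' @param subgroups moderator columns for subgroup analysis.
#' @param subtype_pairs list of stratum pairs to contrast when stratum
#'   rows are present.
#' @param hwe_alpha HWE filter significance level in (0, 1).
#' @param outdir output directory (created if missing); `NULL` skips all
#'   file output and just returns the bundle.
#' @return list of class `run_config`.
#' @export
run_config <- function(input,
                       models = "allele",
                       methods = c("DL_random", "MH_fixed", "IV_fixed"),
                       subgroups = c("ethnic_group", "design"),
                       subtype_pairs = list(c("ERpos", "ERneg"),
                                            c("PRpos", "PRneg"),
                                            c("invasive", "in_situ")),
                       hwe_alpha = 0.05, outdir = NULL) {
  models <- match.arg(models, GENETIC_MODELS, several.ok = TRUE)
  methods <- match.arg(methods, POOL_METHODS, several.ok = TRUE)
  stopifnot(length(models) >= 1, length(methods) >= 1,
            hwe_alpha > 0, hwe_alpha < 1)
  structure(list(input = input, models = models, methods = methods,
                 subgroups = subgroups, subtype_pairs = subtype_pairs,
                 hwe_alpha = hwe_alpha, outdir = outdir),
            class = "run_config")
}

pooled_as_row <- function(p, subgroup = "Total") {
  data.frame(subgroup = subgroup, model = p$model, method = p$method,
             k = p$k, or = p$or_, ci_low = p$ci_low, ci_high = p$ci_high,
             log_or = p$log_or, se = p$se, z = p$z, p_z = p$p_z,
             q = p$q, df_q = p$df, p_q = p$p_q, i2 = p$i2, tau2 = p$tau2,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, dir, name) {
  if (is.null(dir)) return(invisible(NULL))
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits = 6)
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     na = "", row.names = FALSE)
}

#' Run the full meta-analysis pipeline
#'
#' Orchestrates, for one study table: the HWE inclusion filter,
#' per-study effects under each requested genetic model, pooled results
#' for each model x method, subgroup analyses with between-subgroup
#' heterogeneity, subtype contrasts where stratum rows exist,
#' publication-bias diagnostics, leave-one-out influence analysis, and a
#' run manifest. Cells that cannot be computed for a given table (e.g.
#' genotype models on RAF-only studies, bias tests with k < 3) are
#' recorded in `manifest$skipped` and never abort the run. The bundle is
#' deterministic: re-running the same configuration writes identical
#' files.
#'
#' Outputs under `outdir` (when given): `effects_<model>.tsv`,
#' `pooled.tsv` (+ `pooled.json`), `subgroup_<model>_<var>.tsv`,
#' `subtypes_<model>.tsv`, `bias_<model>.json`, `funnel_<model>.tsv`,
#' `influence_<model>.tsv`, `hwe_log.tsv`, `manifest.json`. TSVs carry 6
#' significant digits for human reading; JSON keeps full precision.
#'
#' @param config a [run_config()].
#' @return the report bundle (named list), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- if (inherits(config$input, "study_table")) config$input
           else read_study_table(config$input)
  if (!is.null(config$outdir))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  skipped <- character(0)
  note_skip <- function(what, e) {
    skipped <<- c(skipped, paste0(what, ": ", conditionMessage(e)))
    message("skipping ", what, ": ", conditionMessage(e))
  }
  hwe <- suppressWarnings(filter_studies_by_hwe(table, config$hwe_alpha))
  table <- hwe$table
  bundle <- list(config = config, hwe_log = hwe$log, effects = list(),
                 pooled = list(), subgroups = list(), subtypes = list(),
                 bias = list(), influence = list())
  pooled_rows <- list()
  headline <- config$methods[1]
  for (model in config$models) {
    eff <- tryCatch(suppressWarnings(study_effects(table, model)),
                    error = function(e) { note_skip(paste0("effects/", model), e); NULL })
    if (is.null(eff) || nrow(eff) == 0) next
    bundle$effects[[model]] <- eff
    write_tsv(eff, config$outdir, sprintf("effects_%s.tsv", model))
    for (method in config$methods) {
      p <- tryCatch(switch(method,
             DL_random = pool_dersimonian_laird(eff),
             IV_fixed = pool_inverse_variance(eff),
             MH_fixed = pool_mantel_haenszel(eff)),
           error = function(e) { note_skip(paste(model, method), e); NULL })
      if (is.null(p)) next
      bundle$pooled[[paste(model, method, sep = ".")]] <- p
      pooled_rows[[length(pooled_rows) + 1L]] <- pooled_as_row(p)
    }
    for (v in config$subgroups) {
      sg <- tryCatch(subgroup_analysis(table, model, headline, v),
                     error = function(e) { note_skip(paste("subgroup", model, v), e); NULL })
      if (is.null(sg)) next
      bundle$subgroups[[paste(model, v, sep = ".")]] <- sg
      rows <- do.call(rbind, c(
        lapply(names(sg$groups),
               function(nm) pooled_as_row(sg$groups[[nm]], subgroup = nm)),
        list(pooled_as_row(sg$overall, subgroup = "Total"))))
      rows$q_between <- sg$q_between
      rows$p_between <- sg$p_between
      write_tsv(rows, config$outdir,
                sprintf("subgroup_%s_%s.tsv", model, v))
    }
    for (pair in config$subtype_pairs) {
      sc <- tryCatch(suppressWarnings(
              subtype_contrast(table, model, pair, headline)),
            error = function(e) NULL)  # absent strata are the normal case
      if (is.null(sc)) next
      bundle$subtypes[[paste(model, paste(pair, collapse = "_"),
                             sep = ".")]] <- sc
    }
    br <- tryCatch(bias_report(eff),
                   error = function(e) { note_skip(paste("bias", model), e); NULL })
    if (!is.null(br)) {
      bundle$bias[[model]] <- br
      write_tsv(br$funnel, config$outdir, sprintf("funnel_%s.tsv", model))
      if (!is.null(config$outdir))
        jsonlite::write_json(
          list(egger = br$egger, begg = br$begg),
          file.path(config$outdir, sprintf("bias_%s.json", model)),
          auto_unbox = TRUE, digits = NA)
    }
    infl <- tryCatch(influence_analysis(table, model, headline),
                     error = function(e) { note_skip(paste("influence", model), e); NULL })
    if (!is.null(infl)) {
      bundle$influence[[model]] <- infl
      write_tsv(infl$results, config$outdir,
                sprintf("influence_%s.tsv", model))
    }
  }
  if (length(bundle$subtypes) > 0) {
    st_rows <- do.call(rbind, lapply(names(bundle$subtypes), function(nm) {
      sc <- bundle$subtypes[[nm]]
      do.call(rbind, c(lapply(sc$stratum_pair, function(s)
        pooled_as_row(sc$pooled[[s]], subgroup = s)),
        list(data.frame(subgroup = paste(sc$stratum_pair, collapse = "-"),
                        model = sc$model, method = sc$method, k = sc$k,
                        or = exp(sc$diff), ci_low = NA, ci_high = NA,
                        log_or = sc$diff, se = sc$se_diff, z = sc$z,
                        p_z = sc$p, q = NA, df_q = NA, p_q = NA, i2 = NA,
                        tau2 = NA))))
    }))
    write_tsv(st_rows, config$outdir,
              sprintf("subtypes_%s.tsv", config$models[1]))
  }
  pooled_df <- if (length(pooled_rows) > 0) do.call(rbind, pooled_rows)
    else data.frame(subgroup = character(0), model = character(0),
                    method = character(0), k = integer(0), or = numeric(0),
                    ci_low = numeric(0), ci_high = numeric(0),
                    log_or = numeric(0), se = numeric(0), z = numeric(0),
                    p_z = numeric(0), q = numeric(0), df_q = integer(0),
                    p_q = numeric(0), i2 = numeric(0), tau2 = numeric(0))
  bundle$pooled_table <- pooled_df
  write_tsv(hwe$log, config$outdir, "hwe_log.tsv")
  write_tsv(pooled_df, config$outdir, "pooled.tsv")
  bundle$manifest <- list(
    package = "assocmeta",
    version = as.character(utils::packageVersion("assocmeta")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    models = config$models, methods = config$methods,
    subgroups = config$subgroups, hwe_alpha = config$hwe_alpha,
    input = if (is.character(config$input)) config$input else "in-memory",
    n_studies = sum(is.na(table$stratum)), skipped = skipped)
  if (!is.null(config$outdir)) {
    jsonlite::write_json(lapply(bundle$pooled, unclass),
                         file.path(config$outdir, "pooled.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(bundle$manifest,
                         file.path(config$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(bundle)
}
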