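#' @title Study tables for SNP case-control meta-analysis
#'
#' @description
#' The unit of analysis is the *study*: one row per case-control dataset,
#' carrying either genotype counts (risk-homozygote / heterozygote /
#' non-risk-homozygote in cases and controls) or a risk-allele frequency
#' (RAF) plus subject counts, together with the moderators used for
#' subgroup analysis and meta-regression (ethnic group, study design,
#' control source, genotyping method). Optional extra rows carry
#' case subtypes (ER/PR status, invasiveness) that share the parent
#' study's controls.
#'
#' Tables are stored as plain UTF-8 TSV with one header row and the fixed
#' column set documented in [read_study_table()].
#'
#' @name study_table
NULL

#' Columns of the study-table TSV dialect
#' @keywords internal
STUDY_COLUMNS <- c(
  "study_id", "first_author", "year", "ethnicity", "design",
  "control_source", "genotyping_method", "n_case", "n_control",
  "case_rr", "case_rn", "case_nn", "ctrl_rr", "ctrl_rn", "ctrl_nn",
  "raf_case", "raf_control", "stratum"
)

ETHNIC_GROUPS <- c("White", "EastAsian", "African", "Other")
DESIGNS <- c("GWAS", "CandidateGene")
CONTROL_SOURCES <- c("GP", "HP", "mixed")
STRATA <- c("ERpos", "ERneg", "PRpos", "PRneg", "invasive", "in_situ")

new_study_table <- function(df, provenance = NA_character_) {
  stopifnot(is.data.frame(df))
  structure(df, class = c("study_table", "data.frame"),
            provenance = provenance)
}

#' Default ethnicity mapping shipped with the package
#'
#' Maps free-text ethnicity labels onto the four analysis groups
#' (White, EastAsian, African, Other). The file is a two-column TSV
#' (`label`, `group`) under `inst/extdata/` and can be copied and edited;
#' in particular the grouping of Tunisian studies as African is a mapping
#' choice, not hard-coded.
#'
#' @return data.frame with columns `label` and `group`.
#' @export
default_ethnicity_map <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "ethnicity_map.tsv",
                          package = "assocmeta", mustWork = TRUE)
      cache <<- utils::read.delim(path, stringsAsFactors = FALSE)
    }
    cache
  }
})

#' Map a free-text ethnicity label to an analysis group
#'
#' Multi-population labels (comma-separated, e.g. `"European, Asian"`)
#' are assigned to the first listed population. Labels absent from the
#' mapping fall back to `"Other"` with a warning, never an error, so a
#' table always classifies completely.
#'
#' @param ethnicity_raw character vector of free-text labels.
#' @param mapping data.frame with columns `label`, `group`
#'   (default [default_ethnicity_map()]).
#' @return character vector over `{White, EastAsian, African, Other}`.
#' @examples
#' assign_ethnic_group(c("British", "Korean", "European, Asian"))
#' @export
assign_ethnic_group <- function(ethnicity_raw, mapping = default_ethnicity_map()) {
  stopifnot(all(c("label", "group") %in% names(mapping)))
  first <- trimws(vapply(strsplit(as.character(ethnicity_raw), ","),
                         function(x) x[[1L]], character(1)))
  idx <- match(tolower(first), tolower(mapping$label))
  out <- mapping$group[idx]
  if (anyNA(out)) {
    warning("unmapped ethnicity label(s) assigned to 'Other': ",
            paste(unique(first[is.na(out)]), collapse = ", "),
            call. = FALSE)
    out[is.na(out)] <- "Other"
  }
  out
}

#' Read a study table from TSV
#'
#' Reads the tab-separated study-table dialect: UTF-8, one header row,
#' columns `study_id, first_author, year, ethnicity, design,
#' control_source, genotyping_method, n_case, n_control, case_rr, case_rn,
#' case_nn, ctrl_rr, ctrl_rn, ctrl_nn, raf_case, raf_control, stratum`.
#' Empty optional cells become `NA`, never zero. An `ethnic_group` column
#' is derived from `ethnicity` via `mapping` on read; it is not part of
#' the file format.
#'
#' Rows with an empty `stratum` describe whole studies; rows with a
#' stratum label (`ERpos`, `ERneg`, `PRpos`, `PRneg`, `invasive`,
#' `in_situ`) describe case subtypes of an existing study and carry case
#' data only (controls are shared with the parent row).
#'
#' @param path path to the TSV file.
#' @param mapping ethnicity mapping passed to [assign_ethnic_group()].
#' @return a `study_table` (a validated data.frame).
#' @seealso [write_study_table()], [validate_study_table()]
#' @examples
#' tab <- read_study_table(system.file("extdata", "table1.tsv",
#'                                     package = "assocmeta"))
#' nrow(tab)
#' sum(tab$n_case)
#' @export
read_study_table <- function(path, mapping = default_ethnicity_map()) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("", "NA"))
  missing_cols <- setdiff(STUDY_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    stop_domain("format error: missing mandatory column(s): ",
                paste(missing_cols, collapse = ", "))
  df <- df[STUDY_COLUMNS]
  num_cols <- c("year", "n_case", "n_control", "case_rr", "case_rn",
                "case_nn", "ctrl_rr", "ctrl_rn", "ctrl_nn",
                "raf_case", "raf_control")
  for (col in num_cols) {
    conv <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(conv))
    if (length(bad) > 0)
      stop_domain("format error: non-numeric value in column '", col,
                  "' at data row(s) ", paste(bad, collapse = ", "))
    df[[col]] <- conv
  }
  df$ethnic_group <- if (nrow(df) > 0)
    assign_ethnic_group(df$ethnicity, mapping) else character(0)
  tab <- new_study_table(df, provenance = path)
  validate_study_table(tab)
  tab
}

#' Write a study table to TSV
#'
#' Writes the same dialect [read_study_table()] reads (the derived
#' `ethnic_group` column is dropped), so `read -> write -> read`
#' round-trips every field value exactly.
#'
#' @param table a `study_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(table, path) {
  df <- as.data.frame(table)[STUDY_COLUMNS]
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a study table
#'
#' Enforces the study-table contract: unique study ids among whole-study
#' rows, stratum rows pointing at an existing parent study, subject counts
#' non-negative, genotype triples summing to the subject count, RAFs in
#' \[0, 1\] and consistent with genotype counts when both are present
#' (within 0.005, i.e. two-decimal table rounding), and each whole-study
#' row carrying at least one usable data representation (genotype triples
#' or RAF + N) for cases and for controls. All violations are reported
#' together, addressed by `study_id`.
#'
#' @param table a `study_table` or compatible data.frame.
#' @return `table`, invisibly, on success; otherwise an error.
#' @export
validate_study_table <- function(table) {
  df <- as.data.frame(table)
  errs <- character(0)
  say <- function(...) errs <<- c(errs, paste0(...))
  whole <- is.na(df$stratum)
  ids <- df$study_id[whole]
  if (anyNA(df$study_id) || any(df$study_id == ""))
    say("empty study_id")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0)
    say("duplicate study_id: ", paste(dup, collapse = ", "))
  orphan <- setdiff(df$study_id[!whole], ids)
  if (length(orphan) > 0)
    say("stratum row(s) without parent study: ",
        paste(orphan, collapse = ", "))
  bad_str <- !whole & !(df$stratum %in% STRATA)
  if (any(bad_str))
    say("unknown stratum label for: ",
        paste(df$study_id[bad_str], collapse = ", "))
  if (any(!is.na(df$design[whole]) & !(df$design[whole] %in% DESIGNS)))
    say("design must be one of ", paste(DESIGNS, collapse = "/"))
  if (any(!is.na(df$control_source[whole]) &
          !(df$control_source[whole] %in% CONTROL_SOURCES)))
    say("control_source must be one of ",
        paste(CONTROL_SOURCES, collapse = "/"))

  chk_triple <- function(i, pre, n, side) {
    g <- as.numeric(df[i, paste0(pre, c("_rr", "_rn", "_nn"))])
    if (all(is.na(g))) return(NA)           # absent triple
    if (anyNA(g)) {
      say(df$study_id[i], ": incomplete ", side, " genotype triple")
      return(NA)
    }
    if (any(g < 0))
      say(df$study_id[i], ": negative ", side, " genotype count")
    if (!is.na(n) && sum(g) != n)
      say(df$study_id[i], ": ", side, " genotype counts sum to ", sum(g),
          ", expected n = ", n)
    g
  }
  for (i in seq_len(nrow(df))) {
    n_case <- df$n_case[i]; n_ctrl <- df$n_control[i]
    if (!is.na(n_case) && n_case < 0) say(df$study_id[i], ": negative n_case")
    if (!is.na(n_ctrl) && n_ctrl < 0) say(df$study_id[i], ": negative n_control")
    for (f in c("raf_case", "raf_control")) {
      v <- df[[f]][i]
      if (!is.na(v) && (v < 0 || v > 1))
        say(df$study_id[i], ": ", f, " outside [0, 1]")
    }
    gc <- chk_triple(i, "case", n_case, "case")
    if (!anyNA(gc) && !is.na(df$raf_case[i])) {
      raf <- (2 * gc[1] + gc[2]) / (2 * sum(gc))
      if (abs(raf - df$raf_case[i]) > 0.005)
        say(df$study_id[i], ": raf_case inconsistent with genotype counts")
    }
    case_ok <- !anyNA(gc) || (!is.na(df$raf_case[i]) && !is.na(n_case))
    if (is.na(df$stratum[i])) {
      gt <- chk_triple(i, "ctrl", n_ctrl, "control")
      if (!anyNA(gt) && !is.na(df$raf_control[i])) {
        raf <- (2 * gt[1] + gt[2]) / (2 * sum(gt))
        if (abs(raf - df$raf_control[i]) > 0.005)
          say(df$study_id[i], ": raf_control inconsistent with genotype counts")
      }
      ctrl_ok <- !anyNA(gt) || (!is.na(df$raf_control[i]) && !is.na(n_ctrl))
      if (!case_ok || !ctrl_ok)
        say(df$study_id[i],
            ": needs genotype counts or RAF + N for both cases and controls")
    } else if (!case_ok) {
      say(df$study_id[i], " [", df$stratum[i],
          "]: stratum row needs case genotype counts or raf_case + n_case")
    }
  }
  if (length(errs) > 0)
    stop_domain("invalid study table:\n  ", paste(errs, collapse = "\n  "))
  invisible(table)
}

#' @export
print.study_table <- function(x, ...) {
  whole <- is.na(x$stratum)
  cat("Study table:", sum(whole), "studies,", sum(!whole), "stratum rows\n")
  if (!is.na(attr(x, "provenance")))
    cat("Source:", attr(x, "provenance"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

#' Reconstruct an allele-contrast 2x2 table from RAF and sample size
#'
#' For studies publishing only the risk-allele frequency and subject
#' counts, the allele-contrast table is recovered as
#' `a = round(2 N_case p_case)`, `b = 2 N_case - a` (and likewise for
#' controls), with half rounded away from zero for platform determinism.
#' Row sums equal `2 N` exactly, so alleles are conserved.
#'
#' @param raf_case,raf_control risk-allele frequencies in \[0, 1\].
#' @param n_case,n_control subject counts (> 0).
#' @return a [contrast_table()] for the allele model.
#' @examples
#' allele_table_from_raf(0.54, 4420, 0.50, 17365)
#' @export
allele_table_from_raf <- function(raf_case, n_case, raf_control, n_control) {
  if (raf_case < 0 || raf_case > 1 || raf_control < 0 || raf_control > 1)
    stop_domain("risk-allele frequency outside [0, 1]")
  if (n_case <= 0 || n_control <= 0)
    stop_domain("subject counts must be positive")
  a <- round_half_away(2 * n_case * raf_case)
  c_ <- round_half_away(2 * n_control * raf_control)
  contrast_table(a, 2 * n_case - a, c_, 2 * n_control - c_, model = "allele")
}

#' Expected genotype counts under Hardy-Weinberg equilibrium
#'
#' Returns the real-valued (unrounded) expected counts
#' `n p^2, 2 n p (1 - p), n (1 - p)^2` for risk-allele frequency `p`;
#' used both for the HWE chi-square test expectations and by the study
#' simulator.
#'
#' @param raf risk-allele frequency in \[0, 1\].
#' @param n number of subjects (> 0).
#' @return numeric triple `(rr, rn, nn)`; sums to `n` exactly.
#' @examples
#' genotype_table_from_hwe(0.12, 1000)
#' @export
genotype_table_from_hwe <- function(raf, n) {
  if (raf < 0 || raf > 1) stop_domain("risk-allele frequency outside [0, 1]")
  if (n <= 0) stop_domain("n must be positive")
  c(rr = n * raf^2, rn = 2 * n * raf * (1 - raf), nn = n * (1 - raf)^2)
}
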