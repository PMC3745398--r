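table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "assocmeta", mustWork = TRUE)
}

table1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_study_table(table1_path())
    cache
  }
})

# bare effects frame for pooling/bias tests
make_effects <- function(log_or, se) {
  data.frame(study_id = sprintf("s%02d", seq_along(log_or)),
             model = rep("allele", length(log_or)),
             log_or = log_or, se = se, stringsAsFactors = FALSE)
}

# minimal valid study-table data.frame with genotype counts
geno_row <- function(id, case, ctrl, design = "CandidateGene",
                     ethnicity = "European", stratum = NA_character_) {
  data.frame(study_id = id, first_author = id, year = 2010L,
             ethnicity = ethnicity, design = design, control_source = "GP",
             genotyping_method = "TaqMan",
             n_case = sum(case), n_control = sum(ctrl),
             case_rr = case[1], case_rn = case[2], case_nn = case[3],
             ctrl_rr = ctrl[1], ctrl_rn = ctrl[2], ctrl_nn = ctrl[3],
             raf_case = NA_real_, raf_control = NA_real_,
             stratum = stratum, stringsAsFactors = FALSE)
}

as_study_table <- function(df) {
  df$ethnic_group <- assign_ethnic_group(df$ethnicity)
  assocmeta:::new_study_table(df)
}
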