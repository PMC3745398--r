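test_that("the shipped study table reads completely and matches its margins", {
  tab <- table1()
  expect_s3_class(tab, "study_table")
  expect_equal(nrow(tab), 26)
  expect_equal(sum(tab$n_case), 101529)
  expect_equal(sum(tab$n_control), 167363)
  expect_true(all(is.na(tab$stratum)))
  expect_true(all(tab$ethnic_group %in% c("White", "EastAsian",
                                          "African", "Other")))
  # ethnic-group margins implied by the mapping rules
  expect_equal(as.integer(table(tab$ethnic_group)[c("White", "EastAsian",
                                                    "African", "Other")]),
               c(14L, 6L, 5L, 1L))
})

test_that("a header-only file yields an empty table and write/read round-trips", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(paste(assocmeta:::STUDY_COLUMNS, collapse = "\t"), tmp)
  empty <- read_study_table(tmp)
  expect_equal(nrow(empty), 0)

  out <- tempfile(fileext = ".tsv")
  write_study_table(table1(), out)
  back <- read_study_table(out)
  expect_equal(as.data.frame(back), as.data.frame(table1()),
               ignore_attr = TRUE)
  # and byte-identical on a second write
  out2 <- tempfile(fileext = ".tsv")
  write_study_table(back, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("validation rejects malformed tables with study-addressed messages", {
  df <- as.data.frame(table1())

  bad <- df
  bad[1, c("case_rr", "case_rn", "case_nn")] <- c(100, 200, 100)  # sums 400
  bad$n_case[1] <- 500
  tmp <- tempfile(fileext = ".tsv")
  write_study_table(assocmeta:::new_study_table(bad), tmp)
  expect_error(read_study_table(tmp), "sum to 400.*expected n = 500")
  expect_error(read_study_table(tmp), bad$study_id[1])

  dup <- df
  dup$study_id[2] <- dup$study_id[1]
  write_study_table(assocmeta:::new_study_table(dup), tmp)
  expect_error(read_study_table(tmp), "duplicate study_id")

  miss <- df[, setdiff(names(df), c("raf_case", "ethnic_group"))]
  utils::write.table(miss, tmp, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  expect_error(read_study_table(tmp), "missing mandatory column.*raf_case")

  off <- df
  off$raf_control[3] <- 1.2
  write_study_table(assocmeta:::new_study_table(off), tmp)
  expect_error(read_study_table(tmp), "raf_control outside")
})

test_that("ethnicity mapping follows the grouping rules and is total/idempotent", {
  expect_equal(assign_ethnic_group("British"), "White")
  expect_equal(assign_ethnic_group("Korean"), "EastAsian")
  expect_equal(assign_ethnic_group("Jewish"), "Other")
  # multi-population labels take the first listed population
  expect_equal(assign_ethnic_group("European, Asian"), "White")
  expect_equal(assign_ethnic_group("American, European, African, Asian, Hawaiian"),
               "White")
  # unmapped labels degrade to Other with a warning, never an error
  expect_warning(g <- assign_ethnic_group("Martian"), "unmapped")
  expect_equal(g, "Other")
  # total over every label in the shipped table, and idempotent
  labels <- table1()$ethnicity
  g1 <- assign_ethnic_group(labels)
  expect_false(anyNA(g1))
  expect_identical(assign_ethnic_group(g1), g1)
})

test_that("allele tables reconstructed from RAF conserve alleles", {
  tab <- allele_table_from_raf(0.54, 4420, 0.50, 17365)
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(4774, 4066, 17365, 17365))
  sym <- allele_table_from_raf(0.5, 10, 0.5, 10)
  expect_equal(c(sym$a, sym$b, sym$c, sym$d), c(10, 10, 10, 10))
  bound <- allele_table_from_raf(1.0, 5, 0.0, 5)
  expect_equal(c(bound$a, bound$b, bound$c, bound$d), c(10, 0, 0, 10))
  expect_error(allele_table_from_raf(1.2, 10, 0.5, 10), "outside")

  set.seed(11)
  for (i in 1:50) {
    p1 <- runif(1); p0 <- runif(1)
    n1 <- sample(1:5000, 1); n0 <- sample(1:5000, 1)
    t <- allele_table_from_raf(p1, n1, p0, n0)
    expect_equal(t$a + t$b, 2 * n1)
    expect_equal(t$c + t$d, 2 * n0)
  }
})

test_that("HWE expected genotype counts are exact and sum to n", {
  expect_equal(unname(genotype_table_from_hwe(0.5, 100)), c(25, 50, 25))
  expect_equal(unname(genotype_table_from_hwe(0.0, 50)), c(0, 0, 50))
  expect_equal(unname(genotype_table_from_hwe(0.12, 1000)),
               c(14.4, 211.2, 774.4))
  set.seed(12)
  for (p in runif(25)) {
    n <- sample(1:10000, 1)
    expect_equal(sum(genotype_table_from_hwe(p, n)), n)
  }
})
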