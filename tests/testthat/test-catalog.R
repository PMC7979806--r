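test_that("protein-change grammar classifies the documented forms", {
  cases <- data.frame(
    change = c("S1413F", "E2130K", "p.S1413F", "Q100*", "K200fs",
               "K200Lfs*12", "E300del", "A10_G12del", "T5dup", "G7ins",
               "X100_splice", "M1?", "S100S", "*300W"),
    cons = c("missense", "missense", "missense", "truncation", "truncation",
             "truncation", "inframe", "inframe", "inframe", "inframe",
             "other", "other", "other", "truncation"),
    stringsAsFactors = FALSE)
  got <- parse_protein_change(cases$change)
  expect_equal(as.character(got$consequence), cases$cons)
  expect_equal(got$position[1:2], c(1413L, 2130L))
  expect_equal(got$ref_aa[1], "S")
  expect_equal(got$alt_aa[2], "K")
  expect_equal(got$position[got$protein_change == "Q100*"], 100L)
  expect_equal(got$position[got$protein_change == "E300del"], 300L)
  # unknown grammars carry no position
  expect_true(is.na(got$position[got$protein_change == "X100_splice"]))
  expect_error(parse_protein_change(""), "non-empty")
})

make_fixture_catalog <- function() {
  df <- data.frame(
    gene = c("ATM", "ATM", "ATM", "ATM", "ATR"),
    sample_id = c("s1", "s1", "s2", "s3", "s1"),
    cancer_type = c("colorectal", "colorectal", "endometrial",
                    "colorectal", "breast"),
    protein_change = c("S100F", "Q200*", "S100Y", "E300del", "G50D"),
    stringsAsFactors = FALSE)
  df
}

test_that("load_catalog ingests the TSV dialect and its synonym headers", {
  df <- make_fixture_catalog()
  path <- write_fixture_catalog(df)
  cat <- load_catalog(path, cohort_size = 100)
  expect_s3_class(cat, "mutation_catalog")
  expect_equal(nrow(cat$records), 5)
  expect_equal(as.character(cat$records$consequence),
               c("missense", "truncation", "missense", "inframe",
                 "missense"))
  expect_equal(cat$records$row, 1:5)

  # cBioPortal export headers
  names(df) <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Cancer Type",
                 "Protein Change")
  path2 <- write_fixture_catalog(df)
  cat2 <- load_catalog(path2, cohort_size = 100)
  expect_equal(cat2$records$gene, cat$records$gene)
  expect_equal(cat2$records$protein_change, cat$records$protein_change)

  # empty data section -> zero records
  path3 <- write_fixture_catalog(df[0, ])
  expect_equal(nrow(load_catalog(path3, 10)$records), 0)

  # missing mandatory column named in the error
  path4 <- write_fixture_catalog(df[, -2])
  expect_error(load_catalog(path4, 100), "sample_id")

  # row lacking sample id errors at that row
  df_bad <- make_fixture_catalog()
  df_bad$sample_id[3] <- ""
  expect_error(load_catalog(write_fixture_catalog(df_bad), 100), "row 3")

  # cohort smaller than number of distinct mutated samples
  expect_error(load_catalog(path, cohort_size = 2), "cohort_size")
})

test_that("round trip through the TSV dialect reproduces identical records", {
  cat <- mutation_catalog(make_fixture_catalog(), 100)
  path <- tempfile(fileext = ".tsv")
  write_catalog(cat, path)
  cat2 <- load_catalog(path, 100)
  expect_equal(cat2$records, cat$records)
})

test_that("gene frequency counts a sample once and prints one decimal", {
  cat <- mutation_catalog(make_fixture_catalog(), 100)
  fr <- gene_mutation_frequency(cat, "ATM")
  expect_equal(fr$mutated_samples, 3)  # s1 has two records, counts once
  expect_equal(fr$frequency, 3)
  expect_equal(fr$frequency_pct, 3.0)
  expect_equal(gene_mutation_frequency(cat, "TP53")$frequency_pct, 0)
  expect_true(fr$frequency >= 0 && fr$frequency <= 100)
})

test_that("frequency is monotone non-decreasing as records accrue", {
  set.seed(11)
  df <- data.frame(gene = "ATM",
                   sample_id = sprintf("s%02d", sample(30, 60, TRUE)),
                   cancer_type = "colorectal",
                   protein_change = sprintf("A%dV", sample(500, 60, TRUE)),
                   stringsAsFactors = FALSE)
  freqs <- vapply(seq(5, 60, by = 5), function(k)
    gene_mutation_frequency(mutation_catalog(df[1:k, ], 1000),
                            "ATM")$frequency, numeric(1))
  expect_true(all(diff(freqs) >= 0))
})

test_that("mutated_residues unions positions and honors its filters", {
  cat <- mutation_catalog(make_fixture_catalog(), 100)
  rs <- mutated_residues(cat, "ATM")
  # S100F and S100Y collapse to one entry; truncation/inframe filtered
  expect_equal(rs$position, 100L)
  expect_equal(rs$alt_residues, "F,Y")
  rs_all <- mutated_residues(cat, "ATM",
                             consequences = c("missense", "truncation",
                                              "inframe", "other"))
  expect_equal(rs_all$position, c(100L, 200L, 300L))
  rs_endo <- mutated_residues(cat, "ATM", cancer_type = "endometrial")
  expect_equal(rs_endo$position, 100L)
  expect_error(mutated_residues(cat, "ATM", cancer_type = "lung"),
               "known types")

  # idempotent under record duplication (set semantics)
  cat2 <- mutation_catalog(rbind(make_fixture_catalog(),
                                 make_fixture_catalog()), 100)
  expect_equal(mutated_residues(cat2, "ATM")$position, rs$position)
})

test_that("consequence counts partition the gene's records", {
  cat <- mutation_catalog(make_fixture_catalog(), 100)
  cc <- consequence_counts(cat, "ATM")
  expect_equal(unname(cc), c(2L, 1L, 1L, 0L))
  expect_equal(sum(cc), sum(cat$records$gene == "ATM"))
  empty <- mutation_catalog(make_fixture_catalog()[0, ], 10)
  expect_equal(sum(consequence_counts(empty, "ATM")), 0L)
})
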