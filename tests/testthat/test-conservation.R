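test_that("self-alignment scores the diagonal and is 100% identical", {
  p <- global_align("ACDE", "ACDE")
  expect_equal(p$rows, c("ACDE", "ACDE"))
  expect_equal(p$score, sum(diag(blosum62[c("A", "C", "D", "E"),
                                          c("A", "C", "D", "E")])))
  expect_equal(percent_identity(p)$identity, 100)
})

test_that("a single affine gap run costs open plus extends", {
  p <- global_align("AAAA", "AA")
  # two matches, one gap run of length 2: 2*4 - 10 - 1
  expect_equal(p$score, 2 * blosum62["A", "A"] - 10 - 1)
  expect_equal(sum(strsplit(p$rows[2], "")[[1]] == "-"), 2)
})

test_that("aligner score equals the exhaustive-enumeration oracle", {
  set.seed(42)
  for (rep in 1:60) {
    a <- random_aa_seq(sample(1:6, 1))
    b <- random_aa_seq(sample(1:6, 1))
    got <- global_align(a, b)$score
    want <- oracle_align_score(a, b, blosum62)
    expect_equal(got, want, info = paste(a, b))
  }
})

test_that("illegal characters are rejected with their position", {
  expect_error(global_align("ACBE", "ACDE"), "position 3")
  expect_error(global_align("", "ACDE"), "non-empty")
})

test_that("alignment readers preserve rows verbatim", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">hsa", "AC-E", ">sce", "ACDE"), fa)
  p <- read_alignment(fa, "fasta")
  expect_s3_class(p, "aligned_pair")
  expect_equal(p$rows, c("AC-E", "ACDE"))
  expect_equal(percent_identity(p)$identity, 75)

  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL O(1.2.4) multiple sequence alignment", "", "",
               "hsa      ACDE-F", "sce      ACDWEF", "", "hsa      GHIK",
               "sce      GH-K"), cl)
  p2 <- read_alignment(cl, "clustal")
  expect_equal(p2$rows, c("ACDE-FGHIK", "ACDWEFGH-K"))

  ragged <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">b", "ACD"), ragged)
  expect_error(read_alignment(ragged), "ragged")

  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACDE", ">a", "ACDF"), dup)
  expect_error(read_alignment(dup), "duplicate")
})

test_that("percent identity is symmetric and reports both conventions", {
  set.seed(7)
  for (rep in 1:10) {
    a <- random_aa_seq(sample(4:12, 1))
    b <- random_aa_seq(sample(4:12, 1))
    ab <- percent_identity(global_align(a, b))
    ba <- percent_identity(global_align(b, a))
    expect_equal(ab$identity_columns, ba$identity_columns)
    expect_equal(ab$identity_shorter, ba$identity_shorter)
    # self-alignment score is maximal among alignments of the pair
    self <- global_align(a, a)$score
    expect_gte(self, global_align(a, b)$score)
  }
})

test_that("residue correspondence is monotone and round-trips", {
  p <- aligned_pair("a", "b", c("AB-D", "ABCD"))
  corr <- residue_correspondence(p)
  expect_equal(corr$pairs$pos_a, c(1L, 2L, 3L))
  expect_equal(corr$pairs$pos_b, c(1L, 2L, 4L))
  expect_equal(map_residue(corr, 3), 4L)            # D maps across the gap
  expect_equal(map_residue(corr, 4L, from = "b"), 3L)
  expect_true(is.na(map_residue(corr, 3L, from = "b")))  # C aligns to a gap
  expect_error(map_residue(corr, 9), "out of range")

  # property: monotonicity and identity round trip on random alignments
  set.seed(5)
  for (rep in 1:15) {
    a <- random_aa_seq(sample(2:10, 1))
    b <- random_aa_seq(sample(2:10, 1))
    corr <- residue_correspondence(global_align(a, b))
    expect_true(all(diff(corr$pairs$pos_a) > 0))
    expect_true(all(diff(corr$pairs$pos_b) > 0))
    for (pa in corr$pairs$pos_a)
      expect_equal(map_residue(corr, map_residue(corr, pa), from = "b"), pa)
  }

  # identity alignment maps i -> i
  corr_id <- residue_correspondence(global_align("ACDEF", "ACDEF"))
  expect_equal(map_residue(corr_id, 1:5), 1:5)
})

test_that("conservation calls recover a planted protected core exactly", {
  set.seed(9)
  human <- random_aa_seq(300)
  core <- sort(sample(300, 25))
  orth_far <- simulate_ortholog(human, 0.30, protected = core, seed = 21)
  orth_near <- simulate_ortholog(human, 0.90, protected = core, seed = 22)
  alns <- list(
    mec1 = aligned_pair("human", "mec1", c(human, orth_far$sequence)),
    tel1 = aligned_pair("human", "tel1", c(human, orth_near$sequence)))
  mutated <- sort(sample(300, 60))
  calls <- call_conserved(mutated, human, alns)
  truth <- !(mutated %in% orth_far$truth$substituted) |
           !(mutated %in% orth_near$truth$substituted)
  expect_equal(calls$conserved, truth)
  # protected mutated positions are always conserved
  expect_true(all(calls$conserved[calls$position %in% core]))
  # conserved <=> at least one ortholog identical
  any_ident <- calls$mec1 == "identical" | calls$tel1 == "identical"
  expect_equal(calls$conserved, any_ident)
})

test_that("a residue aligned to gaps in all orthologs is not conserved", {
  human <- "ACDEFGHIK"
  p <- aligned_pair("h", "o", c("ACDEFGHIK", "ACD----IK"))
  calls <- call_conserved(c(2, 5, 6), human, list(orth = p))
  expect_equal(calls$orth, c("identical", "gap", "gap"))
  expect_equal(calls$conserved, c(TRUE, FALSE, FALSE))
  # mismatching human sequence is rejected
  expect_error(call_conserved(1, "ACDEFGHIW", list(orth = p)), "ungap")
})

test_that("HR-block report lists exactly the fully conserved columns", {
  expect_equal(hr_block_alignment(rep("MKVL", 4))$column, 1:4)
  expect_equal(nrow(hr_block_alignment(c("AAAA", "CCCC", "DDDD", "EEEE"))),
               0)
  block <- c("MKVALDN", "MRVALEN", "MSVALFN", "MTVALGN")
  got <- hr_block_alignment(block)
  expect_equal(got$column, c(1L, 3L, 4L, 5L, 7L))
  expect_equal(got$residue, c("M", "V", "A", "L", "N"))
  # gap columns never count
  expect_false(1 %in% hr_block_alignment(c("-KV", "-RV", "-SV"))$column)
  expect_error(hr_block_alignment(c("ABC", "ABCD")), "equal length")
})
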