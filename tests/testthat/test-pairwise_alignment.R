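test_that("identity self-alignment scores 5 per base with no gaps", {
  a <- global_align("ACGT", "ACGT")
  expect_equal(a$score, 20)
  expect_equal(a$n_matches, 4L)
  expect_equal(a$n_gap_columns, 0L)
  expect_equal(percent_identity(a), 100)

  set.seed(5)
  for (n in c(1, 7, 50, 133)) {
    s <- random_dna(n)
    aln <- global_align(s, s)
    expect_equal(aln$score, 5 * n)
    expect_equal(percent_identity(aln), 100)
    expect_equal(aln$n_gap_columns, 0L)
  }
})

test_that("alignment invariants hold: rows reproduce inputs, counts add up", {
  set.seed(6)
  for (rep in 1:20) {
    s1 <- random_dna(sample(1:40, 1))
    s2 <- random_dna(sample(1:40, 1))
    aln <- global_align(s1, s2)
    expect_equal(gsub("-", "", aln$row_a), s1)
    expect_equal(gsub("-", "", aln$row_b), s2)
    expect_equal(nchar(aln$row_a), aln$length)
    expect_equal(aln$n_matches + aln$n_mismatches + aln$n_gap_columns,
                 aln$length)
    # no column has a gap in both rows
    both <- mapply(function(x, y) x == "-" && y == "-",
                   strsplit(aln$row_a, "")[[1]], strsplit(aln$row_b, "")[[1]])
    expect_false(any(both))
  }
})

test_that("optimal score equals the exhaustive-enumeration oracle", {
  expect_equal(global_align("ACGT", "ACT")$score,
               oracle_align_score("ACGT", "ACT"))
  set.seed(7)
  for (rep in 1:40) {
    s1 <- random_dna(sample(1:6, 1))
    s2 <- random_dna(sample(1:6, 1))
    expect_equal(global_align(s1, s2)$score, oracle_align_score(s1, s2),
                 info = paste(s1, s2))
  }
})

test_that("scores agree with an independent affine-gap aligner", {
  skip_if_not_installed("Biostrings")
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                baseOnly = TRUE)
  set.seed(8)
  for (rep in 1:10) {
    s1 <- random_dna(sample(30:120, 1))
    s2 <- random_dna(sample(30:120, 1))
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::DNAString(s1), Biostrings::DNAString(s2),
      substitutionMatrix = m, gapOpening = 10, gapExtension = 0.5,
      type = "global"))
    expect_equal(global_align(s1, s2)$score, ref)
  }
  # protein mode under BLOSUM62 / 11 / 1
  data(BLOSUM62, package = "Biostrings", envir = environment())
  for (rep in 1:6) {
    p1 <- random_protein(sample(20:80, 1))
    p2 <- random_protein(sample(20:80, 1))
    ref <- Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(p1), Biostrings::AAString(p2),
      substitutionMatrix = BLOSUM62, gapOpening = 11, gapExtension = 1,
      type = "global"))
    got <- global_align(seq_record("a", p1, "protein"),
                        seq_record("b", p2, "protein"),
                        scoring_scheme("protein"))$score
    expect_equal(got, ref)
  }
})

test_that("alignment score is symmetric and identity swap-invariant", {
  set.seed(9)
  for (rep in 1:10) {
    s1 <- random_dna(sample(5:60, 1))
    s2 <- random_dna(sample(5:60, 1))
    f <- global_align(s1, s2)
    r <- global_align(s2, s1)
    expect_equal(f$score, r$score)
    # identity is invariant under swapping the two rows of an alignment
    sw <- f
    sw$row_a <- f$row_b
    sw$row_b <- f$row_a
    expect_equal(percent_identity(sw), percent_identity(f))
    expect_equal(percent_identity(sw, "exclude_terminal_gaps"),
                 percent_identity(f, "exclude_terminal_gaps"))
  }
})

test_that("a substitution can never increase identity against a fixed partner", {
  set.seed(10)
  for (rep in 1:10) {
    n <- sample(20:60, 1)
    a <- random_dna(n)
    b <- a
    id0 <- percent_identity(global_align(a, b))
    pos <- sample(n, 1)
    old <- substr(b, pos, pos)
    substr(b, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    id1 <- percent_identity(global_align(a, b))
    expect_lte(id1, id0)
    # and one further substitution from there
    pos2 <- sample(setdiff(seq_len(n), pos), 1)
    b2 <- b
    old2 <- substr(b2, pos2, pos2)
    substr(b2, pos2, pos2) <- sample(setdiff(c("A", "C", "G", "T"), old2), 1)
    expect_lte(percent_identity(global_align(a, b2)), id1)
  }
})

test_that("percent identity uses all columns; terminal-gap exclusion is optional", {
  # constructed alignment: 6 matches, 1 mismatch, 0 gaps -> 6/7
  a <- global_align("ACGTACG", "ACGAACG")
  expect_equal(a$n_matches, 6L)
  expect_equal(a$n_mismatches, 1L)
  expect_equal(percent_identity(a), 100 * 6 / 7, tolerance = 1e-12)

  # a trailing overhang becomes terminal gap columns
  b <- global_align("ACGTACGTAAAA", "ACGTACGT")
  expect_equal(b$n_gap_columns, 4L)
  expect_equal(percent_identity(b), 100 * 8 / 12, tolerance = 1e-12)
  expect_equal(percent_identity(b, denominator = "exclude_terminal_gaps"),
               100, tolerance = 1e-12)
})

test_that("ambiguity codes align but never count as identity matches", {
  a <- global_align("ACGN", "ACGN")
  expect_equal(a$n_matches, 3L)
  expect_equal(a$n_mismatches, 1L)
  expect_equal(percent_identity(a), 75)
})

test_that("empty sequences and alphabet mismatches are rejected", {
  expect_error(global_align("", "ACGT"), "nonempty")
  expect_error(global_align(seq_record("p", "MKV", "protein"), "ACG",
                            scoring_scheme("nucleotide")),
               "alphabet")
  expect_error(scoring_scheme("nucleotide", gap_open = 1, gap_extend = 2))
})
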