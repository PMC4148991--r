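test_that("read_fasta normalizes case, keeps file order and splits headers", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1 some description", "acgt", ">g2", "TTT", "ggg"), f)
  recs <- read_fasta(f, "nucleotide")
  expect_named(recs, c("g1", "g2"))
  expect_equal(recs$g1$residues, "ACGT")
  expect_equal(recs$g1$description, "some description")
  expect_equal(recs$g2$residues, "TTTGGG")
})

test_that("read_fasta enforces unique ids and legal characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g1", "ACGT", ">g1", "TTTT"), f)
  expect_error(read_fasta(f, "nucleotide"), "g1")

  writeLines(c(">g1", "ACGT", ">g2", "ACZT"), f)
  expect_error(read_fasta(f, "nucleotide"), "line 4")

  writeLines(character(), f)
  expect_length(read_fasta(f, "nucleotide"), 0)
})

test_that("FASTA write/read round trip is the identity on random records", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(1:8, 1)
    recs <- lapply(seq_len(n), function(i) {
      seq_record(sprintf("s%02d", i), random_dna(sample(1:250, 1)),
                 "nucleotide", description = sample(c("", "a desc"), 1))
    })
    names(recs) <- vapply(recs, `[[`, "", "id")
    f <- withr::local_tempfile(fileext = ".fasta")
    write_fasta(recs, f)
    back <- read_fasta(f, "nucleotide")
    expect_equal(back, recs)
    # 70-column wrap on write
    expect_true(all(nchar(readLines(f)) <= 71))
  }
})

test_that("written FASTA agrees with an independent reader", {
  skip_if_not_installed("Biostrings")
  set.seed(12)
  recs <- lapply(1:4, function(i)
    seq_record(paste0("r", i), random_dna(120 + i), "nucleotide"))
  names(recs) <- paste0("r", 1:4)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  ref <- Biostrings::readDNAStringSet(f)
  expect_equal(names(ref), names(recs))
  expect_equal(as.character(ref), vapply(recs, `[[`, "", "residues"),
               ignore_attr = TRUE)
})

test_that("seq_record validates alphabet and rejects empty residues", {
  expect_error(seq_record("g", "", "nucleotide"), "nonempty")
  expect_error(seq_record("g", "ACGJ", "nucleotide"), "illegal")
  expect_equal(seq_record("g", "acgtn", "nucleotide")$residues, "ACGTN")
  expect_equal(seq_record("p", "mkv*", "protein")$residues, "MKV*")
})

test_that("hit-table parse is total on valid input and cites bad lines", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("g1\tp9\t45.2\t120\t60\t2\t1\t118\t5\t122\t1e-30\t95.1", f)
  h <- read_hit_table(f)
  expect_equal(nrow(h), 1L)
  expect_equal(h$query_id, "g1")
  expect_equal(h$subject_id, "p9")
  expect_equal(h$pct_identity, 45.2)
  expect_equal(h$aln_length, 120L)
  expect_equal(h$e_value, 1e-30)
  expect_equal(h$bit_score, 95.1)

  writeLines(character(), f)
  expect_equal(nrow(read_hit_table(f)), 0L)

  rows <- c(hit_row("a", "x"), hit_row("b", "y"), hit_row("c", "z"),
            "d\tw\t10")
  writeLines(rows, f)
  expect_error(read_hit_table(f), "line 4")

  writeLines(sub("45.2", "forty", hit_row("a", "x", pid = 45.2)), f)
  expect_error(read_hit_table(f), "unparsable")

  set.seed(3)
  n <- 25
  writeLines(vapply(seq_len(n), function(i)
    hit_row(paste0("q", i), paste0("s", i), ev = 10^-sample(1:40, 1)), ""), f)
  expect_equal(nrow(read_hit_table(f)), n)
})

test_that("translate_cds follows the bacterial code and trims one stop", {
  r <- translate_cds(seq_record("g1", "ATGGCTTAA", "nucleotide"))
  expect_equal(r$residues, "MA")
  expect_equal(r$alphabet, "protein")
  expect_error(translate_cds(seq_record("g1", "ATGTAAGCT", "nucleotide")),
               "internal stop")
  expect_error(translate_cds(seq_record("g1", "ATGGC", "nucleotide")),
               "multiple of 3")
})

test_that("translation matches an independent codon-table lookup", {
  skip_if_not_installed("Biostrings")
  code <- Biostrings::getGeneticCode("11")
  set.seed(21)
  for (rep in 1:5) {
    repeat {
      s <- random_dna(300)
      starts <- seq(1, 300, by = 3)
      aa <- unname(code[substring(s, starts, starts + 2)])
      if (!any(aa == "*")) break
    }
    got <- translate_cds(seq_record("g", s, "nucleotide"))
    expect_equal(got$residues, paste(aa, collapse = ""))
  }
})

test_that("gene_set enforces unique ids and protein/gene id matching", {
  g <- list(seq_record("a", "ATGGCT", "nucleotide"),
            seq_record("b", "ATGAAA", "nucleotide"))
  gs <- gene_set("G1", g)
  expect_equal(length(gs), 2L)
  expect_error(gene_set("G1", c(g, g[1])), "duplicate")
  p_bad <- list(seq_record("a", "MA", "protein"),
                seq_record("c", "MK", "protein"))
  expect_error(gene_set("G1", g, p_bad), "one-to-one")
})

test_that("COG table reader validates category letters", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("g1\tJ", "g2\tK,T"), f)
  tab <- read_cog_table(f)
  expect_equal(tab$g2, c("K", "T"))
  writeLines(c("g1\tJ", "g2\tQQ"), f)
  expect_error(read_cog_table(f), "line 2")
})
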