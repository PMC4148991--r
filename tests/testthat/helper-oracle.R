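# Independent brute-force oracle for affine-gap global alignment: enumerate
# every global alignment (as a sequence of diagonal / gap-in-b / gap-in-a
# moves, no gap/gap columns) and score it directly.  A gap of length L costs
# gap_open + L * gap_extend; a gap opening in one row immediately after a
# gap in the other row is a new gap.  Feasible for sequences up to ~8 long.
oracle_align_score <- function(a, b, match = 5, mismatch = -4,
                               gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(av); m <- length(bv)
  go <- gap_open + gap_extend
  ge <- gap_extend
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i > n && j > m) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (i <= n && j <= m) {
      rec(i + 1L, j + 1L, 0L,
          acc + if (av[i] == bv[j]) match else mismatch)
    }
    if (i <= n) rec(i + 1L, j, 1L, acc - if (last == 1L) ge else go)
    if (j <= m) rec(i, j + 1L, 2L, acc - if (last == 2L) ge else go)
  }
  rec(1L, 1L, 0L, 0)
  best
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}
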