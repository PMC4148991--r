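#' Reciprocal-best-hit parameters
#'
#' Orthologs between two gene sets are detected as reciprocal best hits
#' (RBH) on the protein sequences: two proteins, one per genome, that are
#' each other's highest-scoring global-alignment match.  A candidate pair
#' must additionally reach `min_pct_identity` protein identity and cover at
#' least `min_coverage` of the shorter protein (residue/residue columns over
#' the shorter length).  A shared-k-mer prefilter skips protein pairs with
#' no exact k-mer in common before any alignment is computed; set
#' `prefilter_kmer = NA` to disable it.
#'
#' @param min_pct_identity Minimum protein percent identity (default 30).
#' @param min_coverage Minimum fraction of the shorter protein covered
#'   (default 0.5).
#' @param prefilter_kmer k for the shared-k-mer candidate prefilter
#'   (default 5, protein alphabet); `NA` disables the prefilter.
#' @return An `rbh_params` object.
#' @export
rbh_params <- function(min_pct_identity = 30, min_coverage = 0.5,
                       prefilter_kmer = 5L) {
  stopifnot(min_pct_identity >= 0, min_pct_identity <= 100,
            min_coverage > 0, min_coverage <= 1)
  if (!is.na(prefilter_kmer) && prefilter_kmer < 3L) {
    stop("prefilter_kmer must be >= 3 (or NA to disable)")
  }
  structure(list(min_pct_identity = min_pct_identity,
                 min_coverage = min_coverage,
                 prefilter_kmer = prefilter_kmer),
            class = "rbh_params")
}

# all distinct k-mers of each sequence, as a list of character vectors
.kmer_sets <- function(seqs, k) {
  lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    unique(substring(s, seq_len(n - k + 1L), seq.int(k, n)))
  })
}

# candidate (i, j) pairs sharing at least one k-mer
.kmer_candidates <- function(seqs_a, seqs_b, k) {
  ka <- .kmer_sets(seqs_a, k)
  kb <- .kmer_sets(seqs_b, k)
  ib <- rep.int(seq_along(kb), lengths(kb))
  map_b <- split(ib, unlist(kb, use.names = FALSE))
  pairs_i <- integer(); pairs_j <- integer()
  for (i in seq_along(ka)) {
    hit <- map_b[ka[[i]]]
    js <- unique(unlist(hit, use.names = FALSE))
    if (length(js)) {
      pairs_i <- c(pairs_i, rep.int(i, length(js)))
      pairs_j <- c(pairs_j, js)
    }
  }
  cbind(i = pairs_i, j = pairs_j)
}

# Identity and coverage of one protein pair, from the full alignment.
# Coverage = residue/residue columns over the shorter protein's length.
.pair_stats <- function(prot_a, prot_b, scoring) {
  aln <- global_align(prot_a, prot_b, scoring)
  short <- min(nchar(prot_a$residues), nchar(prot_b$residues))
  list(pct_identity = percent_identity(aln),
       coverage = (aln$n_matches + aln$n_mismatches) / short)
}

#' Detect orthologous gene pairs between two genomes
#'
#' Protein sequences (translated from the CDS when not supplied) are
#' compared all-vs-all by affine-gap global alignment; pairs that are
#' mutual best hits and pass the identity and coverage thresholds are the
#' orthologs.  Ties on score are broken deterministically towards the
#' lexicographically smaller partner id.  Each gene appears in at most one
#' pair.
#'
#' @param set_a,set_b [gene_set] objects.
#' @param params An [rbh_params].
#' @param scoring A protein [scoring_scheme].
#' @return A data frame sorted by `gene_a`: `gene_a`, `gene_b`,
#'   `protein_identity`, `score`.
#' @export
detect_orthologs <- function(set_a, set_b, params = rbh_params(),
                             scoring = scoring_scheme("protein")) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"),
            inherits(params, "rbh_params"))
  if (scoring$mode != "protein") stop("RBH requires a protein scoring scheme")
  set_a <- .with_proteins(set_a)
  set_b <- .with_proteins(set_b)
  pa <- set_a$proteins; pb <- set_b$proteins
  ids_a <- names(pa); ids_b <- names(pb)

  if (is.na(params$prefilter_kmer)) {
    pairs <- as.matrix(expand.grid(i = seq_along(pa), j = seq_along(pb)))
  } else {
    sa <- vapply(pa, `[[`, "", "residues")
    sb <- vapply(pb, `[[`, "", "residues")
    pairs <- .kmer_candidates(sa, sb, params$prefilter_kmer)
  }
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      protein_identity = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  dimnames(pairs) <- NULL

  # score-only scan of every candidate pair (cheap); full alignments are
  # computed lazily below, only while walking down a query's candidates in
  # score order, which yields the same matching as filtering all hits first:
  # the identity/coverage filter does not alter scores.
  enc_a <- lapply(pa, function(r) .encode(r$residues, scoring))
  enc_b <- lapply(pb, function(r) .encode(r$residues, scoring))
  score <- .nw_score_batch_cpp(enc_a, enc_b,
                               cbind(as.integer(pairs[, 1L]),
                                     as.integer(pairs[, 2L])),
                               scoring$matrix, scoring$gap_open,
                               scoring$gap_extend)

  stats_cache <- new.env(parent = emptyenv())
  stats_of <- function(i, j) {
    key <- paste0(i, ":", j)
    if (is.null(stats_cache[[key]])) {
      stats_cache[[key]] <- .pair_stats(pa[[i]], pb[[j]], scoring)
    }
    stats_cache[[key]]
  }
  passes <- function(st) {
    st$pct_identity >= params$min_pct_identity &&
      st$coverage >= params$min_coverage
  }

  # best passing hit per query: walk candidates by descending score,
  # breaking ties towards the lexicographically smaller partner id
  best_passing <- function(query_col, partner_col, partner_ids) {
    rows_by_query <- split(seq_len(nrow(pairs)), pairs[, query_col])
    best <- lapply(rows_by_query, function(rows) {
      ord <- order(-score[rows],
                   partner_ids[pairs[rows, partner_col]], method = "radix")
      for (r in rows[ord]) {
        st <- stats_of(pairs[r, 1L], pairs[r, 2L])
        if (passes(st)) {
          return(c(i = pairs[r, 1L], j = pairs[r, 2L], score = score[r],
                   pid = st$pct_identity))
        }
      }
      NULL
    })
    do.call(rbind, best[!vapply(best, is.null, TRUE)])
  }
  best_a <- best_passing(1L, 2L, ids_b)
  best_b <- best_passing(2L, 1L, ids_a)
  if (is.null(best_a) || is.null(best_b)) return(empty)
  key_a <- paste(best_a[, "i"], best_a[, "j"])
  key_b <- paste(best_b[, "i"], best_b[, "j"])
  mutual <- best_a[key_a %in% key_b, , drop = FALSE]
  if (!nrow(mutual)) return(empty)

  out <- data.frame(gene_a = ids_a[mutual[, "i"]],
                    gene_b = ids_b[mutual[, "j"]],
                    protein_identity = mutual[, "pid"],
                    score = mutual[, "score"], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_a, method = "radix"), , drop = FALSE]
}

#' Average Genomic Identity Of gene Sequences (AGIOS)
#'
#' For every orthologous pair found by [detect_orthologs()], the nucleotide
#' CDS pair is globally aligned and its percent identity (gap columns in
#' the denominator) recorded; AGIOS is the unweighted arithmetic mean of
#' these per-pair identities.  A length-weighted mean (weights = alignment
#' lengths) is reported alongside when `weighted = TRUE`.  When no
#' orthologs are found AGIOS is undefined and reported as `NA`, not 0.
#'
#' @param set_a,set_b [gene_set] objects.
#' @param params An [rbh_params].
#' @param scoring Protein [scoring_scheme] for the RBH stage.
#' @param nt_scoring Nucleotide [scoring_scheme] for the identity stage.
#' @param weighted Also compute the length-weighted mean.
#' @return An `agios_result`: `genome_a`, `genome_b`, `n_orthologs`,
#'   `agios`, optional `agios_weighted`, and `per_pair` (a data frame with
#'   `gene_a`, `gene_b`, `protein_identity`, `nucleotide_identity`).
#' @examples
#' sim <- simulate_pair(simulation_config(n_genes = 5, seed = 1))
#' compute_agios(sim$set_a, sim$set_b)
#' @export
compute_agios <- function(set_a, set_b, params = rbh_params(),
                          scoring = scoring_scheme("protein"),
                          nt_scoring = scoring_scheme("nucleotide"),
                          weighted = FALSE) {
  orth <- detect_orthologs(set_a, set_b, params, scoring)
  n <- nrow(orth)
  nt_id <- numeric(n)
  aln_len <- integer(n)
  for (r in seq_len(n)) {
    aln <- global_align(set_a$genes[[orth$gene_a[r]]],
                        set_b$genes[[orth$gene_b[r]]], nt_scoring)
    nt_id[r] <- percent_identity(aln)
    aln_len[r] <- aln$length
  }
  per_pair <- data.frame(gene_a = orth$gene_a, gene_b = orth$gene_b,
                         protein_identity = orth$protein_identity,
                         nucleotide_identity = nt_id,
                         stringsAsFactors = FALSE)
  res <- list(genome_a = set_a$genome_label, genome_b = set_b$genome_label,
              n_orthologs = n,
              agios = if (n) mean(nt_id) else NA_real_,
              per_pair = per_pair)
  if (weighted) {
    res$agios_weighted <- if (n) sum(nt_id * aln_len) / sum(aln_len)
                          else NA_real_
  }
  structure(res, class = "agios_result")
}

#' @export
print.agios_result <- function(x, ...) {
  cat(sprintf("<agios_result> %s vs %s\n", x$genome_a, x$genome_b))
  cat(sprintf("  orthologs: %d | AGIOS: %s\n", x$n_orthologs,
              if (is.na(x$agios)) "undefined (no orthologs)"
              else sprintf("%.2f%%", x$agios)))
  if (!is.null(x$agios_weighted)) {
    cat(sprintf("  length-weighted AGIOS: %.2f%%\n", x$agios_weighted))
  }
  invisible(x)
}

#' @export
summary.agios_result <- function(object, ...) {
  print(object)
  if (object$n_orthologs) {
    cat("  per-pair nucleotide identity:\n")
    print(summary(object$per_pair$nucleotide_identity))
  }
  invisible(object)
}

#' Multi-genome AGIOS comparison matrix
#'
#' Runs [compute_agios()] on every unordered pair of gene sets and arranges
#' the results in the layout conventional for taxono-genomic species
#' descriptions: per-genome gene counts on the diagonal, ortholog counts in
#' the upper triangle, AGIOS percentages in the lower triangle.
#'
#' @param genomes List of [gene_set] objects with unique labels (>= 2).
#' @param params An [rbh_params].
#' @param scoring,nt_scoring Scoring schemes for the RBH and identity
#'   stages.
#' @return An `agios_matrix` with fields `labels`, `gene_counts`,
#'   `ortholog_counts`, `agios_values` (matrices) and `pairs` (the list of
#'   `agios_result`s).
#' @export
agios_matrix <- function(genomes, params = rbh_params(),
                         scoring = scoring_scheme("protein"),
                         nt_scoring = scoring_scheme("nucleotide")) {
  stopifnot(is.list(genomes), length(genomes) >= 2L)
  labels <- vapply(genomes, `[[`, "", "genome_label")
  if (anyDuplicated(labels)) {
    stop("duplicate genome label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = " "))
  }
  k <- length(genomes)
  n_orth <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  agios <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  pairs <- list()
  for (a in seq_len(k - 1L)) {
    for (b in seq.int(a + 1L, k)) {
      res <- compute_agios(genomes[[a]], genomes[[b]], params, scoring,
                           nt_scoring)
      n_orth[a, b] <- n_orth[b, a] <- res$n_orthologs
      agios[a, b] <- agios[b, a] <- res$agios
      pairs[[paste(labels[a], labels[b], sep = "|")]] <- res
    }
  }
  structure(list(labels = labels,
                 gene_counts = vapply(genomes, length, 0L),
                 ortholog_counts = n_orth, agios_values = agios,
                 pairs = pairs),
            class = "agios_matrix")
}

#' Render an AGIOS matrix in the conventional comparison layout
#'
#' @param x An `agios_matrix`.
#' @return A character matrix: diagonal = gene counts, upper triangle =
#'   ortholog counts, lower triangle = AGIOS percentages (2 dp).
#' @export
format_agios_matrix <- function(x) {
  stopifnot(inherits(x, "agios_matrix"))
  k <- length(x$labels)
  out <- matrix("", k, k, dimnames = list(x$labels, x$labels))
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      out[a, b] <- if (a == b) format(x$gene_counts[a])
      else if (a < b) format(x$ortholog_counts[a, b])
      else if (is.na(x$agios_values[a, b])) "NA"
      else sprintf("%.2f", x$agios_values[a, b])
    }
  }
  out
}

#' @export
print.agios_matrix <- function(x, ...) {
  cat(sprintf("<agios_matrix> %d genomes (diagonal: genes; upper: orthologs; lower: AGIOS %%)\n",
              length(x$labels)))
  print(format_agios_matrix(x), quote = FALSE)
  invisible(x)
}
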