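#' The 25 single-letter COG functional categories
#'
#' @format Character vector of category letters (J = translation, K =
#'   transcription, ..., S = function unknown).
#' @export
COG_CATEGORIES <- c("J", "A", "K", "L", "B", "D", "Y", "V", "T", "M", "N",
                    "Z", "W", "U", "O", "C", "G", "E", "F", "H", "I", "P",
                    "Q", "R", "S")

.COG_DESCRIPTIONS <- c(
  J = "Translation", A = "RNA processing and modification",
  K = "Transcription", L = "Replication, recombination and repair",
  B = "Chromatin structure and dynamics",
  D = "Cell cycle control, mitosis and meiosis", Y = "Nuclear structure",
  V = "Defense mechanisms", T = "Signal transduction mechanisms",
  M = "Cell wall/membrane biogenesis", N = "Cell motility",
  Z = "Cytoskeleton", W = "Extracellular structures",
  U = "Intracellular trafficking and secretion",
  O = "Posttranslational modification, protein turnover, chaperones",
  C = "Energy production and conversion",
  G = "Carbohydrate transport and metabolism",
  E = "Amino acid transport and metabolism",
  F = "Nucleotide transport and metabolism",
  H = "Coenzyme transport and metabolism",
  I = "Lipid transport and metabolism",
  P = "Inorganic ion transport and metabolism",
  Q = "Secondary metabolites biosynthesis, transport and catabolism",
  R = "General function prediction only", S = "Function unknown")

#' G+C content of a set of contigs
#'
#' Counts G and C residues over all contigs.  Among the IUPAC ambiguity
#' codes only `S` (G or C) counts towards G+C; every other code, including
#' `N`, counts 0 towards G+C but is included in the genome size, so the
#' reported percentage is deterministic for any valid input.
#'
#' @param contigs List of nucleotide [seq_record]s (or a character vector
#'   of sequences).
#' @return List with `gc_bp`, `genome_size_bp` and `gc_pct`.
#' @examples
#' gc_content(list(seq_record("c1", "GCGC", "nucleotide")))
#' @export
gc_content <- function(contigs) {
  if (is.character(contigs)) {
    contigs <- lapply(seq_along(contigs), function(i)
      seq_record(paste0("c", i), contigs[[i]], "nucleotide"))
  }
  if (!length(contigs)) stop("contigs must be nonempty")
  gc <- 0; total <- 0
  for (ct in contigs) {
    stopifnot(inherits(ct, "seq_record"), ct$alphabet == "nucleotide")
    n <- nchar(ct$residues)
    total <- total + n
    gc <- gc + n - nchar(gsub("[GCS]", "", ct$residues))
  }
  list(gc_bp = gc, genome_size_bp = total, gc_pct = 100 * gc / total)
}

#' Coding fraction of a genome
#'
#' Total bases covered by gene intervals, with overlapping intervals merged
#' before counting (so a base under two genes is counted once) unless
#' `merge_overlaps = FALSE`, in which case interval lengths are summed
#' as-is.  Intervals are 0-based half-open.
#'
#' @param contigs List of nucleotide [seq_record]s.
#' @param gene_intervals Data frame with columns `contig`, `start`, `end`
#'   (0-based half-open, within contig bounds).
#' @param merge_overlaps Merge overlapping intervals first (default
#'   `TRUE`).
#' @return List with `coding_bp` and `coding_pct`.
#' @export
coding_fraction <- function(contigs, gene_intervals, merge_overlaps = TRUE) {
  gcres <- gc_content(contigs)
  lens <- vapply(contigs, function(x) nchar(x$residues), 0L)
  names(lens) <- vapply(contigs, `[[`, "", "id")
  gi <- gene_intervals
  if (nrow(gi)) {
    stopifnot(all(c("contig", "start", "end") %in% names(gi)))
    bad <- !(gi$contig %in% names(lens))
    if (any(bad)) stop("unknown contig: ", gi$contig[bad][1L])
    if (any(gi$start < 0 | gi$end > lens[gi$contig] | gi$start >= gi$end)) {
      stop("gene interval out of contig bounds")
    }
  }
  coding <- 0
  if (nrow(gi)) {
    for (ctg in unique(gi$contig)) {
      sel <- gi[gi$contig == ctg, , drop = FALSE]
      ir <- IRanges::IRanges(start = sel$start + 1L, end = sel$end)
      if (merge_overlaps) ir <- IRanges::reduce(ir)
      coding <- coding + sum(IRanges::width(ir))
    }
  }
  list(coding_bp = coding, coding_pct = 100 * coding / gcres$genome_size_bp)
}

#' Distribution of genes over COG functional categories
#'
#' A gene assigned to k categories increments all k of them, so the column
#' of counts may sum to more than the number of assigned genes.  Percentages
#' use the total number of protein-coding genes as the denominator (the
#' convention of published genome-description tables) and are rounded to
#' 2 decimal places; the returned table also carries the distinct-gene
#' count so both denominators are explicit.
#'
#' @param assignments Named list mapping gene id to a character vector of
#'   category letters (see [read_cog_table()]).
#' @param protein_genes Total number of protein-coding genes (>= number of
#'   distinct assigned genes).
#' @return A data frame with one row per category plus a final
#'   `"not in COGs"` row: `category`, `count`, `pct`, `description`, with
#'   attributes `genes_in_cogs` and `protein_genes`.
#' @examples
#' cog_distribution(list(g1 = "J", g2 = c("K", "T")), protein_genes = 4)
#' @export
cog_distribution <- function(assignments, protein_genes) {
  stopifnot(protein_genes >= length(assignments))
  cats <- unlist(assignments, use.names = FALSE)
  bad <- setdiff(cats, COG_CATEGORIES)
  if (length(bad)) {
    stop("unknown COG category letter(s): ", paste(unique(bad), collapse = " "))
  }
  counts <- table(factor(cats, levels = COG_CATEGORIES))
  n_assigned <- length(assignments)
  out <- data.frame(category = c(COG_CATEGORIES, "_"),
                    count = c(as.vector(counts), protein_genes - n_assigned),
                    stringsAsFactors = FALSE)
  out$pct <- round(100 * out$count / protein_genes, 2)
  out$description <- c(unname(.COG_DESCRIPTIONS[COG_CATEGORIES]),
                       "Not in COGs")
  attr(out, "genes_in_cogs") <- n_assigned
  attr(out, "protein_genes") <- protein_genes
  out
}

#' Reconstruct a COG assignment list from per-category counts
#'
#' Genome-description tables report only the count of genes per COG
#' category and the number of distinct assigned genes.  This utility builds
#' a concrete assignment list consistent with both: category labels are
#' dealt cyclically over `n_assigned` synthetic gene ids, so every gene
#' receives at least one category, no gene receives the same category
#' twice, and each category's total equals its printed count.  Feasible
#' whenever `sum(counts) >= n_assigned` and no single count exceeds
#' `n_assigned`.
#'
#' @param counts Named integer vector of per-category counts (names are
#'   COG letters).
#' @param n_assigned Number of distinct genes carrying at least one
#'   category.
#' @return A named list mapping synthetic gene ids to category letters,
#'   suitable for [cog_distribution()].
#' @export
build_cog_assignments <- function(counts, n_assigned) {
  stopifnot(all(names(counts) %in% COG_CATEGORIES),
            sum(counts) >= n_assigned, all(counts <= n_assigned))
  ids <- sprintf("gene%05d", seq_len(n_assigned))
  slots <- rep(names(counts), counts)
  gene_of <- ((seq_along(slots) - 1L) %% n_assigned) + 1L
  assignments <- split(slots, ids[gene_of])
  if (any(vapply(assignments, anyDuplicated, 0L) > 0)) {
    stop("counts cannot be dealt without repeating a category on one gene")
  }
  assignments[ids]
}

#' 16S rRNA identity species-delineation check
#'
#' Bacterial taxonomy treats an isolate whose 16S rRNA gene identity with
#' its closest named relative falls below a threshold -- conventionally
#' 98.7% -- as a candidate new species without requiring DNA-DNA
#' hybridization.  The comparison is strict: identity exactly at the
#' threshold is "within known species".
#'
#' @param identity_pct 16S identity in percent, or a `pairwise_alignment`
#'   whose [percent_identity()] is used.
#' @param threshold_pct Delineation threshold (default 98.7).
#' @return A `delineation_verdict`: list with `identity_pct`,
#'   `threshold_pct` and `verdict` (`"candidate new species"` or
#'   `"within known species"`).
#' @examples
#' delineation_check(96.7)
#' @export
delineation_check <- function(identity_pct, threshold_pct = 98.7) {
  stopifnot(threshold_pct > 0, threshold_pct <= 100)
  if (inherits(identity_pct, "pairwise_alignment")) {
    identity_pct <- percent_identity(identity_pct)
  }
  stopifnot(is.numeric(identity_pct), length(identity_pct) == 1L,
            identity_pct >= 0, identity_pct <= 100)
  verdict <- if (identity_pct < threshold_pct) "candidate new species"
             else "within known species"
  structure(list(identity_pct = identity_pct, threshold_pct = threshold_pct,
                 verdict = verdict),
            class = "delineation_verdict")
}

#' @export
print.delineation_verdict <- function(x, ...) {
  cat(sprintf("16S identity %.2f%% vs %.2f%% threshold: %s\n",
              x$identity_pct, x$threshold_pct, x$verdict))
  invisible(x)
}

#' Assemble a genome composition summary
#'
#' Bundles G+C content, coding fraction, gene counts and the COG category
#' distribution into one report of the shape conventional for genome
#' descriptions.
#'
#' @param contigs List of nucleotide [seq_record]s.
#' @param gene_intervals Optional data frame for [coding_fraction()].
#' @param cog_assignments Optional named list for [cog_distribution()].
#' @param protein_genes,rna_genes Gene counts from annotation (RNA genes
#'   default to 0).
#' @return A `genome_summary` object.
#' @export
genome_summary <- function(contigs, protein_genes, rna_genes = 0L,
                           gene_intervals = NULL, cog_assignments = NULL) {
  gcres <- gc_content(contigs)
  coding <- if (!is.null(gene_intervals)) {
    coding_fraction(contigs, gene_intervals)
  } else list(coding_bp = NA_integer_, coding_pct = NA_real_)
  cogs <- if (!is.null(cog_assignments)) {
    cog_distribution(cog_assignments, protein_genes)
  }
  genes_in_cogs <- if (is.null(cogs)) NA_integer_ else attr(cogs, "genes_in_cogs")
  structure(list(genome_size_bp = gcres$genome_size_bp,
                 gc_bp = gcres$gc_bp, gc_pct = gcres$gc_pct,
                 coding_bp = coding$coding_bp, coding_pct = coding$coding_pct,
                 total_genes = protein_genes + rna_genes,
                 rna_genes = rna_genes, protein_genes = protein_genes,
                 genes_in_cogs = genes_in_cogs,
                 not_in_cogs = if (is.na(genes_in_cogs)) NA_integer_
                               else protein_genes - genes_in_cogs,
                 cog_table = cogs),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  pct <- function(num) {
    if (is.na(num)) "" else sprintf("%.2f", 100 * num / x$genome_size_bp)
  }
  gpct <- function(num) {
    if (is.na(num)) "" else sprintf("%.2f", 100 * num / x$total_genes)
  }
  cat("<genome_summary>\n")
  cat(sprintf("  Genome size (bp)       %12s  %6s\n",
              format(x$genome_size_bp, big.mark = ","), "100"))
  if (!is.na(x$coding_bp)) {
    cat(sprintf("  DNA coding region (bp) %12s  %6s\n",
                format(x$coding_bp, big.mark = ","), pct(x$coding_bp)))
  }
  cat(sprintf("  DNA G+C content (bp)   %12s  %6s\n",
              format(x$gc_bp, big.mark = ","), pct(x$gc_bp)))
  cat(sprintf("  Total genes            %12s  %6s\n", x$total_genes, "100"))
  cat(sprintf("  RNA genes              %12s  %6s\n", x$rna_genes,
              gpct(x$rna_genes)))
  cat(sprintf("  Protein-coding genes   %12s  %6s\n", x$protein_genes,
              gpct(x$protein_genes)))
  if (!is.na(x$genes_in_cogs)) {
    cat(sprintf("  Genes assigned to COGs %12s  %6.2f\n", x$genes_in_cogs,
                100 * x$genes_in_cogs / x$protein_genes))
  }
  if (!is.null(x$cog_table)) {
    cat("  COG category distribution:\n")
    tb <- x$cog_table
    for (r in seq_len(nrow(tb))) {
      cat(sprintf("    %s %5d %6.2f  %s\n", tb$category[r], tb$count[r],
                  tb$pct[r], tb$description[r]))
    }
  }
  invisible(x)
}
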