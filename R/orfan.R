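#' ORFan classification policy
#'
#' A gene is an ORFan when none of its database hits is good enough to count
#' as evidence of homology.  The dual-threshold rule used here: a hit
#' qualifies when its E-value is at most `e_long` (default 1e-3) for
#' alignments longer than `len_cut` amino acids (default 80), or at most the
#' stricter `e_short` (default 1e-5) for alignments of `len_cut` or fewer
#' amino acids.  Short alignments get the stricter cut because they reach
#' small E-values more easily by chance.
#'
#' The boundary case of exactly `len_cut` columns is routed to the short
#' (stricter) branch, and E-values are compared with `<=`.
#'
#' `literal_rule = TRUE` inverts the predicate so that a gene is flagged
#' when it *does* have a sub-threshold hit.  Read literally, some published
#' method descriptions state the rule this way; taken at face value it would
#' label well-conserved genes as ORFans, which contradicts ORFans being a
#' small minority of any genome, so the conventional reading is the default
#' and the literal one is kept only for exact-wording replication.
#'
#' @param e_long E-value threshold for long alignments.
#' @param len_cut Alignment-length cut in amino-acid columns.
#' @param e_short E-value threshold for short alignments
#'   (`e_short <= e_long`).
#' @param literal_rule Flip the predicate (see above).
#' @return An `orfan_policy` object.
#' @export
orfan_policy <- function(e_long = 1e-3, len_cut = 80L, e_short = 1e-5,
                         literal_rule = FALSE) {
  stopifnot(e_short <= e_long, len_cut >= 1)
  structure(list(e_long = e_long, len_cut = len_cut, e_short = e_short,
                 literal_rule = literal_rule),
            class = "orfan_policy")
}

#' Does a similarity hit qualify as homology evidence?
#'
#' @param aln_length Alignment length(s) in amino-acid columns.
#' @param e_value E-value(s); recycled against `aln_length`.
#' @param policy An [orfan_policy].
#' @return Logical vector: `TRUE` where the hit passes the dual-threshold
#'   rule.
#' @examples
#' qualifying_hit(100, 1e-4)  # long branch: TRUE
#' qualifying_hit(50, 1e-4)   # short branch needs <= 1e-5: FALSE
#' @export
qualifying_hit <- function(aln_length, e_value, policy = orfan_policy()) {
  stopifnot(inherits(policy, "orfan_policy"))
  (aln_length > policy$len_cut & e_value <= policy$e_long) |
    (aln_length <= policy$len_cut & e_value <= policy$e_short)
}

#' Classify ORFans from a similarity-hit table
#'
#' A gene is an ORFan when it has no qualifying hit (genes with no hits at
#' all are ORFans).  Self-hits (`query_id == subject_id`) are ignored, and
#' hits whose query is not in `gene_ids` are dropped with a warning.
#'
#' @param gene_ids Character vector of all protein-coding gene ids.
#' @param hits Data frame of hits as returned by [read_hit_table()] (needs
#'   `query_id`, `subject_id`, `aln_length`, `e_value`).
#' @param policy An [orfan_policy].
#' @return An `orfan_report`: `n_genes`, `orfan_ids`, `n_orfans`,
#'   `fraction` (percent), and `detail` (per-gene data frame with `gene_id`,
#'   `n_hits`, `n_qualifying`, `is_orfan`).
#' @examples
#' hits <- data.frame(query_id = "g1", subject_id = "p1",
#'                    aln_length = 120, e_value = 1e-30)
#' classify_orfans(c("g1", "g2"), hits)
#' @export
classify_orfans <- function(gene_ids, hits, policy = orfan_policy()) {
  stopifnot(is.character(gene_ids))
  if (!length(gene_ids)) stop("gene_ids must be nonempty")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  unknown <- setdiff(unique(hits$query_id), gene_ids)
  if (length(unknown)) {
    warning("ignoring hits for ", length(unknown),
            " query id(s) not in gene_ids")
    hits <- hits[hits$query_id %in% gene_ids, , drop = FALSE]
  }
  q <- qualifying_hit(hits$aln_length, hits$e_value, policy)
  if (policy$literal_rule) q <- !q
  n_hits <- table(factor(hits$query_id, levels = gene_ids))
  n_qual <- table(factor(hits$query_id[q], levels = gene_ids))
  is_orfan <- as.vector(n_qual) == 0L
  detail <- data.frame(gene_id = gene_ids,
                       n_hits = as.vector(n_hits),
                       n_qualifying = as.vector(n_qual),
                       is_orfan = is_orfan, stringsAsFactors = FALSE)
  structure(list(n_genes = length(gene_ids),
                 orfan_ids = gene_ids[is_orfan],
                 n_orfans = sum(is_orfan),
                 fraction = 100 * sum(is_orfan) / length(gene_ids),
                 detail = detail),
            class = "orfan_report")
}

#' @export
print.orfan_report <- function(x, ...) {
  cat(sprintf("<orfan_report> %d / %d genes are ORFans (%.2f%%)\n",
              x$n_orfans, x$n_genes, x$fraction))
  invisible(x)
}
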