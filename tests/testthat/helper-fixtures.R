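# Shared fixture builders.

# gene_set of random unrelated CDS (no stops), for negative controls
random_gene_set <- function(label, n_genes, n_codons = 100) {
  genes <- lapply(seq_len(n_genes), function(i) {
    repeat {
      s <- random_dna(3 * n_codons)
      p <- tryCatch(translate_cds(seq_record("x", s, "nucleotide")),
                    error = function(e) NULL)
      if (!is.null(p)) break
    }
    seq_record(sprintf("%s_g%03d", label, i), s, "nucleotide")
  })
  gene_set(label, genes)
}

# relabel a gene_set's ids (prefix swap) without touching the sequences
relabel_gene_set <- function(gs, new_label) {
  genes <- lapply(gs$genes, function(g) {
    seq_record(sub("^[^_]+", new_label, g$id), g$residues, g$alphabet)
  })
  gene_set(new_label, genes)
}

# a minimal valid 12-column hit row
hit_row <- function(q, s, pid = 50, len = 100, ev = 1e-10, bits = 200) {
  paste(q, s, pid, len, 5, 1, 1, len, 1, len, format(ev), bits, sep = "\t")
}

hit_frame <- function(query_id, subject_id, aln_length, e_value) {
  data.frame(query_id = query_id, subject_id = subject_id,
             aln_length = aln_length, e_value = e_value,
             stringsAsFactors = FALSE)
}
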