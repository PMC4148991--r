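#' Configuration for the genome-pair simulator
#'
#' The simulator draws an ancestral set of protein-coding genes and derives
#' descendants from it under a site-wise substitution model, so orthology
#' detection and AGIOS can be validated against known truth.  Defaults
#' emulate the regime in which gene-based identity statistics discriminate
#' closely related bacterial species: a couple of hundred genes of typical
#' bacterial CDS length, high-G+C composition (62%), and a few percent
#' per-site divergence.
#'
#' @param n_genes Number of ancestral genes (default 200).
#' @param gene_length_range Gene length range in codons, inclusive
#'   (default 100--500; minimum 30).
#' @param gc_target Target G+C fraction of the generated CDS (default
#'   0.62); achieved to within about 2 percentage points on average, since
#'   stop-codon avoidance perturbs the raw base frequencies.
#' @param divergence_d Per-site substitution probability applied to
#'   descendant B (default 0.05); must be <= 0.75, the saturation point of
#'   a uniform substitution model.
#' @param p_gene_loss Per-gene loss probability, applied independently per
#'   descendant (default 0).
#' @param indel_rate Per-gene probability of one codon-length indel in
#'   descendant B (default 0).
#' @param seed Integer seed; the simulation is fully reproducible from it.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_genes = 200L, gene_length_range = c(100L, 500L),
                              gc_target = 0.62, divergence_d = 0.05,
                              p_gene_loss = 0, indel_rate = 0, seed = 1L) {
  stopifnot(n_genes >= 1, length(gene_length_range) == 2L,
            gene_length_range[1L] >= 30L,
            gene_length_range[1L] <= gene_length_range[2L],
            gc_target > 0.05, gc_target < 0.95,
            divergence_d >= 0, divergence_d <= 0.75,
            p_gene_loss >= 0, p_gene_loss < 1,
            indel_rate >= 0, indel_rate <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = as.integer(gene_length_range),
                 gc_target = gc_target, divergence_d = divergence_d,
                 p_gene_loss = p_gene_loss, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.is_stop <- function(codon_mat) {
  # codon_mat: 3 x n matrix of base codes (1..4: A C G T)
  s <- paste0(.BASES[codon_mat[1L, ]], .BASES[codon_mat[2L, ]],
              .BASES[codon_mat[3L, ]])
  s %in% .STOP_CODONS
}

# draw one gene of n_codons codons with no stop codons, base probs p
.draw_gene <- function(n_codons, p) {
  m <- matrix(sample.int(4L, 3L * n_codons, replace = TRUE, prob = p),
              nrow = 3L)
  repeat {
    bad <- which(.is_stop(m))
    if (!length(bad)) break
    m[, bad] <- sample.int(4L, 3L * length(bad), replace = TRUE, prob = p)
  }
  m
}

# mutate each site with probability d to a uniformly chosen different base,
# redrawing any codon's mutations if they would create a stop codon
.mutate_gene <- function(m, d) {
  if (d == 0) return(m)
  n_sites <- length(m)
  hit <- which(stats::runif(n_sites) < d)
  if (!length(hit)) return(m)
  out <- m
  shift <- sample.int(3L, length(hit), replace = TRUE)
  out[hit] <- ((m[hit] - 1L + shift) %% 4L) + 1L
  repeat {
    bad <- which(.is_stop(out))
    if (!length(bad)) break
    for (cd in bad) {
      sites <- hit[(hit - 1L) %/% 3L + 1L == cd]
      repeat {
        out[sites] <- ((m[sites] - 1L +
                          sample.int(3L, length(sites), replace = TRUE)) %% 4L) + 1L
        if (!.is_stop(out[, cd, drop = FALSE])) break
      }
    }
  }
  out
}

.collapse <- function(m) paste(.BASES[as.vector(m)], collapse = "")

# one codon-length insertion or deletion at a random codon boundary
.apply_indel <- function(m, p) {
  n <- ncol(m)
  if (stats::runif(1) < 0.5 && n > 30L) {          # deletion
    m[, -sample.int(n, 1L), drop = FALSE]
  } else {                                          # insertion
    pos <- sample.int(n + 1L, 1L) - 1L
    ins <- .draw_gene(1L, p)
    cbind(m[, seq_len(pos), drop = FALSE], ins,
          m[, seq_len(n - pos) + pos, drop = FALSE])
  }
}

.run_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate a pair of gene sets descended from a common ancestor
#'
#' Ancestral genes are drawn codon-wise, avoiding stop codons, with base
#' frequencies tuned to `gc_target`.  Descendant A is the ancestor itself;
#' descendant B mutates each site independently with probability
#' `divergence_d` to a uniformly chosen different base, redrawing any
#' mutation set that would create an internal stop codon.  Genes are then
#' lost from each descendant independently with probability `p_gene_loss`.
#' The truth table records the *realized* per-gene identity (the fraction
#' of sites actually unchanged between the two copies, before any indel),
#' which is the recovery target for AGIOS -- using the realized rather than
#' the nominal divergence removes Monte-Carlo slack from downstream checks.
#'
#' Gene ids encode ancestry (`anc0007_A` / `anc0007_B`), so orthology
#' recovery is checkable by id without alignment.
#'
#' @param config A [simulation_config].
#' @param labels Genome labels for the two descendants.
#' @return A list with `set_a`, `set_b` ([gene_set]s) and `truth`, a list
#'   with `table` (data frame: `gene_id`, `present_in_A`, `present_in_B`,
#'   `realized_identity_pct`), `shared_gene_ids`, `mean_realized_identity`
#'   and `seed`.
#' @examples
#' sim <- simulate_pair(simulation_config(n_genes = 10, seed = 42))
#' sim$truth$mean_realized_identity
#' @export
simulate_pair <- function(config = simulation_config(),
                          labels = c("A", "B")) {
  stopifnot(inherits(config, "simulation_config"), length(labels) == 2L)
  .run_with_seed(config$seed, {
    gc <- config$gc_target
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    n <- config$n_genes
    ids <- sprintf("anc%04d", seq_len(n))
    lens <- sample(seq.int(config$gene_length_range[1L],
                           config$gene_length_range[2L]), n, replace = TRUE)
    genes_a <- list(); genes_b <- list()
    ident <- numeric(n)
    for (g in seq_len(n)) {
      anc <- .draw_gene(lens[g], p)
      mut <- .mutate_gene(anc, config$divergence_d)
      ident[g] <- 100 * mean(anc == mut)
      if (config$indel_rate > 0 && stats::runif(1) < config$indel_rate) {
        mut <- .apply_indel(mut, p)
      }
      genes_a[[g]] <- seq_record(paste0(ids[g], "_", labels[1L]),
                                 .collapse(anc), "nucleotide")
      genes_b[[g]] <- seq_record(paste0(ids[g], "_", labels[2L]),
                                 .collapse(mut), "nucleotide")
    }
    in_a <- stats::runif(n) >= config$p_gene_loss
    in_b <- stats::runif(n) >= config$p_gene_loss
    # a descendant must keep at least one gene
    if (!any(in_a)) in_a[1L] <- TRUE
    if (!any(in_b)) in_b[1L] <- TRUE
    shared <- in_a & in_b
    truth_tab <- data.frame(gene_id = ids, present_in_A = in_a,
                            present_in_B = in_b,
                            realized_identity_pct = ident,
                            stringsAsFactors = FALSE)
    list(set_a = gene_set(labels[1L], genes_a[in_a]),
         set_b = gene_set(labels[2L], genes_b[in_b]),
         truth = list(table = truth_tab,
                      shared_gene_ids = ids[shared],
                      mean_realized_identity =
                        if (any(shared)) mean(ident[shared]) else NA_real_,
                      seed = config$seed))
  })
}

#' Simulate a star phylogeny: several descendants of one ancestor
#'
#' All descendants share the ancestor drawn from `config`; descendant `k`
#' is mutated with `divergences[k]` and suffers gene loss at
#' `config$p_gene_loss`.  Because divergence accumulates independently on
#' each branch, the expected identity between two descendants is the
#' product of their per-branch retention rates, so AGIOS over the resulting
#' matrix must order pairs by total branch divergence.
#'
#' @param config A [simulation_config]; its `divergence_d` is ignored in
#'   favour of `divergences`.
#' @param divergences Numeric vector (length >= 2) of per-site divergence
#'   for each descendant.
#' @param labels Genome labels (default `"A"`, `"B"`, ...).
#' @return A list with `sets` (list of [gene_set]s), `truth` (data frame:
#'   `gene_id`, one `present_in_<label>` column per descendant, and one
#'   `identity_<label>` column giving realized identity to the ancestor)
#'   and `pair_identity`, a labelled matrix of realized site identity
#'   between each pair of descendants over their shared genes.
#' @export
simulate_star <- function(config = simulation_config(),
                          divergences = c(0.02, 0.05, 0.10),
                          labels = LETTERS[seq_along(divergences)]) {
  stopifnot(inherits(config, "simulation_config"), length(divergences) >= 2L,
            length(labels) == length(divergences),
            all(divergences >= 0), all(divergences <= 0.75))
  .run_with_seed(config$seed, {
    gc <- config$gc_target
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    n <- config$n_genes
    k <- length(divergences)
    ids <- sprintf("anc%04d", seq_len(n))
    lens <- sample(seq.int(config$gene_length_range[1L],
                           config$gene_length_range[2L]), n, replace = TRUE)
    anc <- lapply(lens, .draw_gene, p = p)
    desc <- vector("list", k)
    ident <- matrix(NA_real_, n, k, dimnames = list(ids, labels))
    for (d in seq_len(k)) {
      desc[[d]] <- lapply(seq_len(n), function(g) {
        m <- .mutate_gene(anc[[g]], divergences[d])
        ident[g, d] <<- 100 * mean(anc[[g]] == m)
        m
      })
    }
    present <- matrix(stats::runif(n * k) >= config$p_gene_loss, n, k,
                      dimnames = list(ids, labels))
    for (d in seq_len(k)) if (!any(present[, d])) present[1L, d] <- TRUE

    sets <- lapply(seq_len(k), function(d) {
      keep <- which(present[, d])
      gene_set(labels[d], lapply(keep, function(g)
        seq_record(paste0(ids[g], "_", labels[d]), .collapse(desc[[d]][[g]]),
                   "nucleotide")))
    })
    pair_id <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
    for (a in seq_len(k - 1L)) {
      for (b in seq.int(a + 1L, k)) {
        shared <- which(present[, a] & present[, b])
        if (length(shared)) {
          v <- vapply(shared, function(g)
            100 * mean(desc[[a]][[g]] == desc[[b]][[g]]), 0)
          pair_id[a, b] <- pair_id[b, a] <- mean(v)
        }
      }
    }
    truth <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
    for (d in seq_len(k)) truth[[paste0("present_in_", labels[d])]] <- present[, d]
    for (d in seq_len(k)) truth[[paste0("identity_", labels[d])]] <- ident[, d]
    list(sets = sets, truth = truth, pair_identity = pair_id,
         seed = config$seed)
  })
}

#' Write a simulated pair to disk
#'
#' Emits `<label>.ffn` (nucleotide CDS) and `<label>.faa` (translated
#' proteins) for each descendant, plus `truth.tsv` (tab-separated:
#' `gene_id`, `present_in_A`, `present_in_B`, `realized_identity_pct`).
#'
#' @param sim Result of [simulate_pair()].
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (gs in list(sim$set_a, sim$set_b)) {
    write_fasta(gs$genes, file.path(dir, paste0(gs$genome_label, ".ffn")))
    write_fasta(.with_proteins(gs)$proteins,
                file.path(dir, paste0(gs$genome_label, ".faa")))
  }
  utils::write.table(sim$truth$table, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
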