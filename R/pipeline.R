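#' Run configuration for the comparison pipeline
#'
#' Collects every tunable the pipeline honours in one validated object.
#' Overrides can also be read from a flat `key = value` text file via
#' `read_run_config()`; values given directly to `run_config()` win over
#' file values, so a run is fully described by (inputs, config file,
#' direct overrides, seed).
#'
#' @param rbh An [rbh_params].
#' @param orfan An [orfan_policy].
#' @param delineation_threshold 16S delineation threshold in percent.
#' @param nt_scoring,aa_scoring [scoring_scheme]s for the nucleotide and
#'   protein stages.
#' @param out_dir Output directory for report files.
#' @param seed Integer seed forwarded to any simulation step.
#' @return A `run_config` object.
#' @export
run_config <- function(rbh = rbh_params(), orfan = orfan_policy(),
                       delineation_threshold = 98.7,
                       nt_scoring = scoring_scheme("nucleotide"),
                       aa_scoring = scoring_scheme("protein"),
                       out_dir = ".", seed = 1L) {
  stopifnot(inherits(rbh, "rbh_params"), inherits(orfan, "orfan_policy"),
            inherits(nt_scoring, "scoring_scheme"),
            inherits(aa_scoring, "scoring_scheme"),
            nt_scoring$mode == "nucleotide", aa_scoring$mode == "protein",
            delineation_threshold > 0, delineation_threshold <= 100)
  structure(list(rbh = rbh, orfan = orfan,
                 delineation_threshold = delineation_threshold,
                 nt_scoring = nt_scoring, aa_scoring = aa_scoring,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' @param path Path to a flat `key = value` config file.  Recognized keys:
#'   `min_pct_identity`, `min_coverage`, `prefilter_kmer`, `e_long`,
#'   `len_cut`, `e_short`, `delineation_threshold`, `gap_open`,
#'   `gap_extend`, `match`, `mismatch`, `out_dir`, `seed`.  Lines starting
#'   with `#` are comments.
#' @rdname run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L) stop("unparsable config line: ", ln)
    kv[[m[2]]] <- type.convert(trimws(m[3]), as.is = TRUE)
  }
  num <- function(key, default) if (is.null(kv[[key]])) default else kv[[key]]
  run_config(
    rbh = rbh_params(num("min_pct_identity", 30), num("min_coverage", 0.5),
                     num("prefilter_kmer", 5L)),
    orfan = orfan_policy(num("e_long", 1e-3), num("len_cut", 80L),
                         num("e_short", 1e-5)),
    delineation_threshold = num("delineation_threshold", 98.7),
    nt_scoring = scoring_scheme("nucleotide", match = num("match", 5),
                                mismatch = num("mismatch", -4),
                                gap_open = num("gap_open", 10),
                                gap_extend = num("gap_extend", 0.5)),
    out_dir = num("out_dir", "."), seed = num("seed", 1L))
}

#' Run the multi-genome comparison pipeline end to end
#'
#' Reads two or more gene sets (nucleotide CDS FASTA, with proteins
#' auto-translated or taken from a sibling `.faa` file of the same stem),
#' computes the full AGIOS matrix, and writes three reports to
#' `config$out_dir`: `agios_matrix.tsv` (the comparison grid: diagonal gene
#' counts, upper ortholog counts, lower AGIOS), `ortholog_pairs.tsv`
#' (per-pair detail: genome pair, gene ids, protein and nucleotide
#' identity) and `summary.json`.  Outputs are deterministic: identical
#' inputs and config give byte-identical files.
#'
#' @param config A [run_config].
#' @param genome_paths Character vector (length >= 2) of CDS FASTA paths;
#'   the genome label is the file stem.
#' @return Invisibly, the `agios_matrix`, with attribute `files` naming the
#'   written reports.
#' @export
run_pipeline <- function(config, genome_paths) {
  stopifnot(inherits(config, "run_config"))
  if (length(genome_paths) < 2L) {
    stop("matrix mode requires at least 2 genome FASTA paths")
  }
  missing <- genome_paths[!file.exists(genome_paths)]
  if (length(missing)) stop("unreadable input: ", missing[1L])
  genomes <- lapply(genome_paths, function(p) {
    label <- sub("\\.[^.]*$", "", basename(p))
    genes <- read_fasta(p, "nucleotide")
    faa <- file.path(dirname(p), paste0(label, ".faa"))
    prot <- if (file.exists(faa)) read_fasta(faa, "protein")
    gene_set(label, genes, prot)
  })
  mat <- agios_matrix(genomes, config$rbh, config$aa_scoring,
                      config$nt_scoring)

  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  f_mat <- file.path(config$out_dir, "agios_matrix.tsv")
  f_pairs <- file.path(config$out_dir, "ortholog_pairs.tsv")
  f_json <- file.path(config$out_dir, "summary.json")

  grid <- format_agios_matrix(mat)
  utils::write.table(cbind(genome = rownames(grid), as.data.frame(grid)),
                     f_mat, sep = "\t", quote = FALSE, row.names = FALSE)
  detail <- do.call(rbind, lapply(mat$pairs, function(r) {
    if (!r$n_orthologs) return(NULL)
    cbind(genome_a = r$genome_a, genome_b = r$genome_b, r$per_pair)
  }))
  if (is.null(detail)) {
    detail <- data.frame(genome_a = character(), genome_b = character(),
                         gene_a = character(), gene_b = character(),
                         protein_identity = numeric(),
                         nucleotide_identity = numeric())
  }
  utils::write.table(detail, f_pairs, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  pair_summaries <- lapply(mat$pairs, function(r)
    list(genome_a = r$genome_a, genome_b = r$genome_b,
         n_orthologs = r$n_orthologs, agios = r$agios))
  jsonlite::write_json(
    list(genomes = mat$labels,
         gene_counts = as.list(stats::setNames(mat$gene_counts, mat$labels)),
         pairs = unname(pair_summaries)),
    f_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  attr(mat, "files") <- c(matrix = f_mat, pairs = f_pairs, json = f_json)
  invisible(mat)
}
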