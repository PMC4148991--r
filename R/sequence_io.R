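#' Sequence records and gene sets
#'
#' A `seq_record` is one FASTA entry: an `id` (the first whitespace-delimited
#' token of the header), a free-text `description` (the remainder of the
#' header) and the residue string, stored uppercase and validated against a
#' declared alphabet.  A `gene_set` bundles the nucleotide CDS of one genome
#' with an optional parallel set of protein sequences sharing the same ids.
#'
#' Alphabets: `"nucleotide"` accepts the four bases plus the IUPAC ambiguity
#' codes (`RYSWKMBDHVN`); `"protein"` accepts the 20 amino acids plus `X`
#' (unknown) and `*` (stop).
#'
#' @param id Record identifier (unique within a file or gene set).
#' @param residues Residue string; validated and stored uppercase.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param description Free-text description (may be empty).
#' @return `seq_record()` returns a `seq_record` object.
#' @examples
#' seq_record("g1", "acgt", "nucleotide")
#' @export
seq_record <- function(id, residues, alphabet = c("nucleotide", "protein"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("record '", id, "': residues must be nonempty")
  bad <- .illegal_chars(residues, alphabet)
  if (length(bad)) {
    stop("record '", id, "': illegal ", alphabet, " character(s): ",
         paste(unique(bad), collapse = " "))
  }
  structure(list(id = id, description = description, residues = residues,
                 alphabet = alphabet),
            class = "seq_record")
}

.alphabet_chars <- function(alphabet) {
  if (alphabet == "nucleotide") {
    c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
  } else {
    c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")
  }
}

.illegal_chars <- function(residues, alphabet) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  ch[!ch %in% .alphabet_chars(alphabet)]
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s [%s, %d residues]\n", x$id, x$alphabet,
              nchar(x$residues)))
  invisible(x)
}

#' Read and write FASTA files
#'
#' `read_fasta()` parses a FASTA file into a list of [seq_record] objects,
#' in file order.  Residues are uppercased and validated against `alphabet`;
#' an illegal character or a duplicated id is a hard error naming the
#' offending line or id.  An empty file yields an empty list.
#' `write_fasta()` writes records back out, wrapping residue lines at 70
#' columns, so that a read/write round trip reproduces ids, descriptions and
#' sequences exactly.
#'
#' @param path File path.
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @return `read_fasta()` returns a named list of `seq_record`s (names are
#'   the record ids); `write_fasta()` returns `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' write_fasta(list(seq_record("g1", "ACGT", "nucleotide")), f)
#' read_fasta(f, "nucleotide")
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  id <- NULL
  desc <- ""
  chunks <- character()
  first_line <- NA_integer_

  flush <- function() {
    if (is.null(id)) return()
    res <- paste(chunks, collapse = "")
    if (!nzchar(res)) {
      stop("record '", id, "' (line ", first_line, "): empty sequence")
    }
    if (id %in% names(records)) stop("duplicate sequence id '", id, "'")
    records[[id]] <<- seq_record(id, res, alphabet, desc)
  }

  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    if (startsWith(ln, ">")) {
      flush()
      hdr <- sub("^>\\s*", "", ln)
      id <- sub("\\s.*$", "", hdr)
      if (!nzchar(id)) stop("line ", k, ": header with no id")
      if (id %in% names(records)) stop("duplicate sequence id '", id, "'")
      desc <- if (grepl("\\s", hdr)) sub("^\\S+\\s+", "", hdr) else ""
      chunks <- character()
      first_line <- k
    } else if (nzchar(trimws(ln))) {
      if (is.null(id)) stop("line ", k, ": sequence data before any header")
      seg <- toupper(gsub("\\s", "", ln))
      bad <- .illegal_chars(seg, alphabet)
      if (length(bad)) {
        stop("line ", k, ": illegal ", alphabet, " character(s): ",
             paste(unique(bad), collapse = " "))
      }
      chunks <- c(chunks, seg)
    }
  }
  flush()
  records
}

#' @param records List of [seq_record] objects.
#' @param width Residue-line wrap width (columns).
#' @rdname read_fasta
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (r in records) {
    hdr <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", hdr), con)
    n <- nchar(r$residues)
    starts <- seq.int(1L, n, by = width)
    writeLines(substring(r$residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Gene sets: the CDS/protein duality of a genome
#'
#' @param genome_label Genome label (unique within a comparison).
#' @param genes Named list of nucleotide [seq_record]s (the CDS).
#' @param proteins Optional named list of protein [seq_record]s with ids
#'   matching `genes` one-to-one.  When absent, proteins are derived on
#'   demand by [translate_cds()].
#' @return A `gene_set` object.
#' @export
gene_set <- function(genome_label, genes, proteins = NULL) {
  stopifnot(is.character(genome_label), length(genome_label) == 1L,
            nzchar(genome_label), is.list(genes), length(genes) > 0L)
  ids <- vapply(genes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate gene id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = " "))
  }
  names(genes) <- ids
  if (!is.null(proteins)) {
    pids <- vapply(proteins, `[[`, "", "id")
    if (!setequal(pids, ids) || length(pids) != length(ids)) {
      stop("protein ids must match gene ids one-to-one")
    }
    names(proteins) <- pids
    proteins <- proteins[ids]
  }
  structure(list(genome_label = genome_label, genes = genes,
                 proteins = proteins),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes%s\n", x$genome_label, length(x$genes),
              if (is.null(x$proteins)) "" else " (+proteins)"))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

# Ensure a gene_set carries proteins, translating the CDS where needed.
# Genes whose CDS fails translation (internal stop, length not a multiple
# of 3) are dropped from the protein set but kept in the gene list, so they
# are excluded from orthology detection yet still counted as genes.
.with_proteins <- function(gs) {
  if (!is.null(gs$proteins)) return(gs)
  prot <- list()
  for (g in gs$genes) {
    p <- tryCatch(translate_cds(g), error = function(e) NULL)
    if (!is.null(p)) prot[[p$id]] <- p
  }
  if (!length(prot)) {
    stop("gene set '", gs$genome_label,
         "': no protein sequences and no translatable CDS")
  }
  gs$proteins <- prot
  gs
}

# Bacterial genetic code (translation table 11).  Coincides with the
# standard code for codon translation; the tables differ only in permitted
# start codons, which do not matter here.
.CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate a coding sequence
#'
#' Translates a nucleotide CDS under the bacterial genetic code (translation
#' table 11).  A single trailing stop codon is trimmed; an internal stop
#' codon, a length that is not a multiple of three, or an ambiguous base are
#' hard errors (the pipeline's simulated and curated CDS are unambiguous by
#' construction).
#'
#' @param record A nucleotide [seq_record] whose length is a multiple of 3.
#' @param table Genetic code identifier; only `"11"` (bacterial) is
#'   supported.
#' @return A protein [seq_record] with the same id and description.
#' @examples
#' translate_cds(seq_record("g1", "ATGGCTTAA", "nucleotide"))
#' @export
translate_cds <- function(record, table = "11") {
  stopifnot(inherits(record, "seq_record"), record$alphabet == "nucleotide")
  if (!identical(as.character(table), "11")) {
    stop("unsupported genetic code table: ", table)
  }
  n <- nchar(record$residues)
  if (n %% 3L != 0L) {
    stop("record '", record$id, "': CDS length ", n,
         " is not a multiple of 3")
  }
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(record$residues, starts, starts + 2L)
  aa <- .CODON_TABLE[codons]
  if (anyNA(aa)) {
    stop("record '", record$id, "': ambiguous codon(s): ",
         paste(unique(codons[is.na(aa)]), collapse = " "))
  }
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    stop("record '", record$id, "': internal stop codon at codon ",
         which(aa == "*")[1L])
  }
  if (!length(aa)) stop("record '", record$id, "': CDS is a bare stop codon")
  seq_record(record$id, paste(aa, collapse = ""), "protein",
             record$description)
}

#' Read a 12-column tabular similarity-hit file
#'
#' Parses the standard 12-column tab-separated search layout (`qseqid
#' sseqid pident length mismatch gapopen qstart qend sstart send evalue
#' bitscore`, i.e. "outfmt 6").  Columns 5--10 are parsed for validation but
#' ignored downstream; the ORFan rule consumes only the query/subject ids,
#' percent identity, alignment length (amino-acid columns), E-value and bit
#' score.
#'
#' @param path File path.
#' @return A data frame with one row per hit: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `e_value`, `bit_score`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(query_id = character(), subject_id = character(),
                      pct_identity = numeric(), aln_length = integer(),
                      e_value = numeric(), bit_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 12L)
  if (length(short)) {
    stop("line ", short[1L], ": expected 12 tab-separated columns, found ",
         lengths(fields)[short[1L]])
  }
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", col)))
    if (anyNA(v)) stop("line ", which(is.na(v))[1L], ": unparsable ", what)
    v
  }
  pid <- num(3L, "percent identity")
  len <- num(4L, "alignment length")
  # columns 5-10 validated as numeric, then dropped
  for (col in 5:10) num(col, paste("column", col))
  ev <- num(11L, "E-value")
  bs <- num(12L, "bit score")
  if (any(pid < 0 | pid > 100)) {
    stop("line ", which(pid < 0 | pid > 100)[1L],
         ": percent identity outside [0,100]")
  }
  if (any(len < 1)) stop("line ", which(len < 1)[1L], ": alignment length < 1")
  if (any(ev < 0)) stop("line ", which(ev < 0)[1L], ": negative E-value")
  data.frame(query_id = vapply(fields, `[[`, "", 1L),
             subject_id = vapply(fields, `[[`, "", 2L),
             pct_identity = pid, aln_length = as.integer(len),
             e_value = ev, bit_score = bs, stringsAsFactors = FALSE)
}

#' Read a COG assignment table
#'
#' Two tab-separated columns: gene id, comma-joined COG category letters
#' (e.g. `"J"` or `"K,T"`).  A gene absent from the table is "not in COGs".
#'
#' @param path File path.
#' @return A named list mapping gene id to a character vector of category
#'   letters.
#' @export
read_cog_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (k in seq_along(lines)) {
    f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("line ", k, ": expected 2 tab-separated columns")
    cats <- toupper(trimws(strsplit(f[[2]], ",", fixed = TRUE)[[1]]))
    cats <- cats[nzchar(cats)]
    if (!length(cats)) stop("line ", k, ": no categories for gene ", f[[1]])
    bad <- setdiff(cats, COG_CATEGORIES)
    if (length(bad)) {
      stop("line ", k, ": unknown COG category letter(s): ",
           paste(bad, collapse = " "))
    }
    if (f[[1]] %in% names(out)) stop("line ", k, ": duplicate gene id ", f[[1]])
    out[[f[[1]]]] <- cats
  }
  out
}
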