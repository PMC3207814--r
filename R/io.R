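#' @name tagdex-io
#' @title Plain-text format helpers
#' @description Thin wrappers around Biostrings and base table readers for
#'   the formats the pipeline exchanges: FASTA/FASTQ sequence sets, the
#'   ortholog table, per-target count tables and GMT gene-set collections.
NULL

#' Write sequences to FASTA
#' @param seqs named character vector or [Biostrings::DNAStringSet].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "XStringSet")) seqs <- as_dna_set(as_char_seqs(seqs))
  Biostrings::writeXStringSet(seqs, path, format = "fasta")
  invisible(path)
}

#' Read a FASTA file
#' @param path input file.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  names(x) <- sub("\\s.*$", "", names(x))   # drop description
  x
}

#' Write a simulated read library to FASTQ (Sanger/Phred+33)
#' @param lib a library from [simulate_reads()], or a named character vector
#'   of read sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lib, path) {
  reads <- if (is.list(lib)) lib$reads else lib
  dna <- as_dna_set(as_char_seqs(reads))
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(dna)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file
#' @param path input file.
#' @return A named [Biostrings::DNAStringSet] (qualities are not retained;
#'   no pipeline stage consumes them).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Read/write the ortholog table
#'
#' Tab-separated, three columns: `refB_gene`, `refA_gene`, `cardinality`
#' (`one2one`, `one2many` or `none`; `refA_gene` is empty for `none` rows).
#'
#' @param path file path.
#' @return `read_ortholog_table`: a data.frame; `write_ortholog_table`:
#'   `path`, invisibly.
#' @export
read_ortholog_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("refB_gene", "refA_gene", "cardinality")
  if (!all(need %in% names(df)))
    stop("ortholog table must have columns ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$cardinality), c("one2one", "one2many", "none"))
  if (length(bad))
    stop("unknown cardinality label(s): ", paste(bad, collapse = ", "))
  df[need]
}

#' @param orthologs ortholog data.frame.
#' @rdname read_ortholog_table
#' @export
write_ortholog_table <- function(orthologs, path) {
  write.table(orthologs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write per-target count tables (TSV: target, count)
#' @param path file path.
#' @return `read_count_table`: a data.frame with `target` and integer
#'   `count`.
#' @export
read_count_table <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("target", "count") %in% names(df)))
    stop("count table must have columns target, count")
  df$count <- as.integer(df$count)
  df
}

#' @param counts count data.frame.
#' @rdname read_count_table
#' @export
write_count_table <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one term per line, tab-separated `id`, `description`,
#' members. Terms must be unique and non-empty.
#'
#' @param path GMT file.
#' @return A named list of character vectors with a `description` attribute
#'   per element, class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop("GMT line ", short[1], ": fewer than 3 fields")
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(ids[lengths(sets) == 0L], collapse = ", "))
  names(sets) <- ids
  attr(sets, "description") <- setNames(vapply(parts, `[[`, character(1), 2L), ids)
  class(sets) <- "gene_set_collection"
  sets
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection>", length(x), "terms;",
      sum(lengths(unclass(x))), "memberships\n")
  invisible(x)
}

#' Bundled top-20 gene count table
#'
#' The printed 76 bp / 39 bp read counts of the twenty genes with the
#' highest corrected fold differences in the naked mole-rat vs mouse liver
#' comparison, shipped as a plain-text fixture. Serves as a worked example
#' and as the oracle for the fold statistic and its ranking.
#'
#' @return A [gene_counts()] data.frame with additional columns
#'   `printed_fold` (the fold as published) and `printed_rank`.
#' @examples
#' t1 <- table1_counts()
#' corrected_fold(t1$focal_76, t1$ref_76)[t1$gene == "A2m"]
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_counts.tsv", package = "tagdex",
                      mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- gene_counts(df$gene, df$focal_76, df$ref_76, df$focal_39, df$ref_39)
  out$printed_fold <- df$printed_fold
  out$printed_rank <- df$rank
  out
}
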