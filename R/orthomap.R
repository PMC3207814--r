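#' @name orthomap
#' @title Contig-to-ortholog assignment across two reference species
#' @description Assigns each focal-species contig to a single reference-A
#'   gene by the e-value disambiguation rule -- a hit is unambiguous if it is
#'   either the sole significant hit (e < 0.05) or at least two orders of
#'   magnitude better than the runner-up -- applied to hits pooled across the
#'   two reference transcriptomes and collapsed through 1:1 orthology.
NULL

#' Load 12-column tabular BLAST hits
#'
#' Standard tabular dialect (qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore). The subject species is inferred
#' from a supplied subject-to-species map.
#'
#' @param path tab-separated hit file with at least 12 columns and no header.
#' @param species_map named character vector mapping subject ids to `"refA"`
#'   or `"refB"`.
#' @return A `blast_hits` data.frame: `query`, `subject`, `species`,
#'   `evalue`, `bitscore`.
#' @export
load_blast_tab <- function(path, species_map) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short))
    stop("parse error at line ", short[1], ": fewer than 12 columns")
  evalue <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 11L)))
  if (anyNA(evalue))
    stop("parse error at line ", which(is.na(evalue))[1],
         ": non-numeric e-value")
  bits <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 12L)))
  subject <- vapply(parts, `[[`, character(1), 2L)
  missing <- setdiff(unique(subject), names(species_map))
  if (length(missing))
    stop("subject(s) absent from species map: ",
         paste(missing, collapse = ", "))
  blast_hits(query = vapply(parts, `[[`, character(1), 1L),
             subject = subject,
             species = unname(species_map[subject]),
             evalue = evalue, bitscore = bits)
}

blast_hits <- function(query, subject, species, evalue, bitscore) {
  if (any(evalue < 0)) stop("e-values must be non-negative")
  df <- data.frame(query = query, subject = subject, species = species,
                   evalue = evalue, bitscore = bitscore)
  class(df) <- c("blast_hits", "data.frame")
  df
}

#' Built-in desk-scale hit generator
#'
#' A BLAST substitute for simulated data: per contig and cDNA, shared k-mers
#' are chained ungapped on the best diagonal and the matched bases `M` give a
#' pseudo-bitscore `S = 2 M` and pseudo-e-value `m n 2^-S` for query length
#' `m` and total database length `n`, floored at 1e-300. Pairs sharing no
#' k-mer emit no hit. Deterministic.
#'
#' @param contigs named character vector or [Biostrings::DNAStringSet].
#' @param cdnas named reference cDNA sequences (may pool both species).
#' @param k seed length (>= 8).
#' @param species optional named character vector mapping cDNA ids to
#'   `"refA"`/`"refB"`; defaults to `"refA"` for all.
#' @return A `blast_hits` data.frame.
#' @export
hits_builtin <- function(contigs, cdnas, k = 11L, species = NULL) {
  if (k < 8L) stop("input error: k must be >= 8")
  contigs <- as_char_seqs(contigs)
  cdnas <- as_char_seqs(cdnas)
  if (is.null(species)) species <- setNames(rep("refA", length(cdnas)), names(cdnas))
  res <- .kmer_matched_bases_cpp(unname(contigs), unname(cdnas), as.integer(k))
  if (!nrow(res))
    return(blast_hits(character(0), character(0), character(0),
                      numeric(0), numeric(0)))
  m <- nchar(contigs)[res$query]
  n_db <- sum(nchar(cdnas))
  S <- 2 * res$matched
  log10e <- log10(m) + log10(n_db) - S * log10(2)
  evalue <- pmax(10^pmax(log10e, -300), 1e-300)
  subject <- names(cdnas)[res$target]
  blast_hits(query = names(contigs)[res$query], subject = subject,
             species = unname(species[subject]),
             evalue = evalue, bitscore = S)
}

# the disambiguation rule on gene-level best e-values
classify_evalues <- function(evalues, e_max = 0.05, clearance = 100) {
  if (!length(evalues)) return("NO_SIGNIFICANT_HIT")
  best <- min(evalues)
  if (best >= e_max) return("NO_SIGNIFICANT_HIT")
  if (length(evalues) == 1L) return("UNIQUE")
  second <- sort(evalues, partial = 2)[2]
  if (best == 0) return(if (second > 0) "CLEAR_BEST" else "AMBIGUOUS")
  if (best * clearance <= second) "CLEAR_BEST" else "AMBIGUOUS"
}

#' Classify one contig's hits (single-reference rule)
#'
#' Hits are first collapsed to one best (minimum) e-value per subject gene;
#' the contig is `UNIQUE` if exactly one gene is hit and its e-value is below
#' `e_max`, `CLEAR_BEST` if the best gene-level e-value is below `e_max` and
#' at least `clearance`-fold smaller than the runner-up (boundary inclusive;
#' a best of exactly 0 beats any positive runner-up, two zeros tie as
#' `AMBIGUOUS`), `AMBIGUOUS` if significant but not separable, and
#' `NO_SIGNIFICANT_HIT` if nothing reaches `e_max`.
#'
#' @param hits a `blast_hits` data.frame for a single query contig.
#' @param e_max significance ceiling on the best e-value (default 0.05).
#' @param clearance required ratio between best and second-best e-values
#'   (default 100, i.e. two orders of magnitude).
#' @param gene_map optional named vector collapsing subject transcript ids to
#'   gene ids (default: subjects are genes).
#' @return A one-row `contig_assignment` data.frame: `contig`, `gene`
#'   (`NA` unless assigned), `status`.
#' @examples
#' h <- tagdex:::blast_hits("c1", c("gA", "gB"), "refA", c(1e-8, 1e-5), c(50, 30))
#' classify_contig(h)   # CLEAR_BEST: three orders of clearance
#' @export
classify_contig <- function(hits, e_max = 0.05, clearance = 100,
                            gene_map = NULL) {
  if (nrow(hits) && length(unique(hits$query)) != 1L)
    stop("input error: hits must share a single query")
  contig <- if (nrow(hits)) hits$query[1] else NA_character_
  gene <- if (is.null(gene_map)) hits$subject else unname(gene_map[hits$subject])
  ev <- tapply(hits$evalue, gene, min)
  status <- classify_evalues(as.numeric(ev), e_max, clearance)
  assigned <- if (status %in% c("UNIQUE", "CLEAR_BEST"))
    names(ev)[which.min(ev)] else NA_character_
  contig_assignment(contig, assigned, status)
}

contig_assignment <- function(contig, gene, status) {
  df <- data.frame(contig = contig, gene = gene, status = status)
  class(df) <- c("contig_assignment", "data.frame")
  df
}

check_ortholog_table <- function(orthologs) {
  need <- c("refB_gene", "refA_gene", "cardinality")
  if (!all(need %in% names(orthologs)))
    stop("ortholog table must have columns ", paste(need, collapse = ", "))
  rows_per_b <- table(orthologs$refB_gene)
  for (gb in names(rows_per_b)) {
    card <- unique(orthologs$cardinality[orthologs$refB_gene == gb])
    if (length(card) > 1L)
      stop("input error: mixed cardinality labels for ", gb)
    n <- rows_per_b[[gb]]
    if (card == "one2one" && n != 1L)
      stop("input error: one2one label with ", n, " rows for ", gb)
    if (card == "one2many" && n < 2L)
      stop("input error: one2many label with a single row for ", gb)
  }
  invisible(orthologs)
}

#' Combine reference-A and reference-B hits through 1:1 orthology
#'
#' Per contig: (1) each reference-B subject is mapped to its 1:1 reference-A
#' ortholog where one exists; reference-B genes with no, multiple, or `none`
#' ortholog rows form their own unmappable pseudo-groups; (2) hits collapse
#' to ortholog-group level keeping the minimum e-value per group (a
#' reference-A gene and its 1:1 reference-B ortholog are one group); (3) the
#' disambiguation rule of [classify_contig()] is applied to the group-level
#' e-values; (4) if the winning group is reachable only via a reference-B
#' gene with no or multiple reference-A orthologs the contig is
#' `ORTHOLOGY_FAIL` and gets no assignment.
#'
#' @param hits a `blast_hits` data.frame (species column must be `"refA"` or
#'   `"refB"`).
#' @param orthologs ortholog table (`refB_gene`, `refA_gene`, `cardinality`).
#' @param e_max,clearance as in [classify_contig()].
#' @param gene_map optional named vector collapsing subject transcript ids to
#'   gene ids.
#' @param per_species if `TRUE`, classify reference-A hits alone first and
#'   fall back to reference-B hits only when A is not unambiguous (a stricter
#'   variant; the pooled group-collapsed rule is the default).
#' @param queries optional character vector of all query contig ids; contigs
#'   without any hit then appear as `NO_SIGNIFICANT_HIT` rows.
#' @return A `contig_assignment` data.frame, one row per contig.
#' @export
combine_dual_reference <- function(hits, orthologs, e_max = 0.05,
                                   clearance = 100, gene_map = NULL,
                                   per_species = FALSE, queries = NULL) {
  check_ortholog_table(orthologs)
  one2one <- orthologs[orthologs$cardinality == "one2one" &
                         !is.na(orthologs$refA_gene), , drop = FALSE]
  b2a <- setNames(one2one$refA_gene, one2one$refB_gene)

  res <- lapply(split(seq_len(nrow(hits)), hits$query), function(idx) {
    h <- hits[idx, , drop = FALSE]
    gene <- if (is.null(gene_map)) h$subject else unname(gene_map[h$subject])
    if (per_species) {
      a <- h$species == "refA"
      ca <- if (any(a)) classify_contig(h[a, , drop = FALSE], e_max, clearance,
                                        gene_map) else NULL
      if (!is.null(ca) && ca$status %in% c("UNIQUE", "CLEAR_BEST")) return(ca)
      hb <- h[!a, , drop = FALSE]
      if (!nrow(hb)) return(contig_assignment(h$query[1], NA_character_,
                                              if (is.null(ca)) "NO_SIGNIFICANT_HIT" else ca$status))
      cb <- classify_contig(hb, e_max, clearance, gene_map)
      if (!cb$status %in% c("UNIQUE", "CLEAR_BEST")) return(cb)
      ga <- b2a[cb$gene]
      if (is.na(ga))
        return(contig_assignment(h$query[1], NA_character_, "ORTHOLOGY_FAIL"))
      return(contig_assignment(h$query[1], unname(ga), cb$status))
    }
    is_b <- h$species == "refB"
    group <- gene
    ok <- rep(TRUE, nrow(h))
    mapped <- b2a[gene[is_b]]
    group[is_b] <- ifelse(is.na(mapped), paste0("refB:", gene[is_b]), mapped)
    ok[is_b] <- !is.na(mapped)
    ev <- tapply(h$evalue, group, min)
    grp_ok <- tapply(ok, group, any)   # reachable via refA or a 1:1 bridge
    status <- classify_evalues(as.numeric(ev), e_max, clearance)
    if (!status %in% c("UNIQUE", "CLEAR_BEST"))
      return(contig_assignment(h$query[1], NA_character_, status))
    win <- names(ev)[which.min(ev)]
    if (!grp_ok[[win]])
      return(contig_assignment(h$query[1], NA_character_, "ORTHOLOGY_FAIL"))
    contig_assignment(h$query[1], win, status)
  })
  out <- do.call(rbind, unname(res))
  if (is.null(out))
    out <- contig_assignment(character(0), character(0), character(0))
  if (!is.null(queries)) {
    hitless <- setdiff(queries, out$contig)
    if (length(hitless))
      out <- rbind(out, contig_assignment(hitless, NA_character_,
                                          "NO_SIGNIFICANT_HIT"))
  }
  out[order(out$contig), , drop = FALSE]
}

#' Background gene set for over-representation analysis
#'
#' The distinct reference-A genes carrying at least one unambiguously
#' assigned contig: the universe against which enrichment of the
#' over-expressed list is judged.
#'
#' @param assignments a `contig_assignment` data.frame.
#' @return Sorted character vector of reference-A gene ids.
#' @export
background_genes <- function(assignments) {
  sort(unique(assignments$gene[assignments$status %in%
                                 c("UNIQUE", "CLEAR_BEST")]))
}
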