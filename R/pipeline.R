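#' End-to-end pipeline on simulated data
#'
#' Runs the full analysis on one synthetic dataset: simulate the three
#' transcriptomes, contigs and both tag libraries; align focal reads to the
#' contigs and reference reads to the reference-A cDNAs with the built-in
#' aligner; apply the positive-score gate (both sides) and the 3'-window
#' rule (reference side, where whole cDNAs are the targets); generate
#' contig-vs-cDNA hits; disambiguate contigs to reference-A genes through
#' the dual-reference orthology rule; and aggregate read counts per gene
#' into a fold-change table.
#'
#' @param config a [sim_config()].
#' @param k_align seed length of the read aligner.
#' @param max_mismatch mismatch cap of the read aligner.
#' @param k_hits seed length of the contig hit generator.
#' @param e_max,clearance disambiguation parameters (see
#'   [classify_contig()]).
#' @param window 3'-window size for the reference library (nt).
#' @param pseudocount pseudocount of the fold statistic.
#' @return A list: `sim` (transcriptomes + truth), `contigs`, `assignments`,
#'   `background`, `counts` (a [gene_counts()] table over all reference-A
#'   genes), `folds` (fold-change table), `stats` (per-library filter
#'   statistics), `truth` (per-gene truth with a `covered` flag).
#' @examples
#' \donttest{
#' res <- run_sim_pipeline(sim_config(n_genes = 30, library_size_focal = 5000,
#'                                    library_size_ref = 5000, seed = 2))
#' head(res$folds)
#' }
#' @export
run_sim_pipeline <- function(config, k_align = 20L, max_mismatch = 4L,
                             k_hits = 11L, e_max = 0.05, clearance = 100,
                             window = 1050L, pseudocount = 100) {
  sim <- simulate_transcriptomes(config)
  ctg <- simulate_contigs(sim$focal, config)
  truth <- sim$truth
  truth$covered <- truth$gene %in% ctg$map$gene

  focal_expr <- setNames(truth$focal_frac, truth$gene)
  ref_expr <- setNames(truth$ref_frac, truth$gene)
  focal_lib <- simulate_reads(sim$focal, focal_expr, config,
                              library_size = config$library_size_focal,
                              seed = config$seed + 2L)
  ref_keep <- ref_expr > 0
  ref_lib <- simulate_reads(sim$refA, ref_expr[ref_keep], config,
                            library_size = config$library_size_ref,
                            seed = config$seed + 3L)

  # focal side: reads -> contigs (no 3' window: contigs are fragments)
  focal_al <- align_builtin(focal_lib$reads, ctg$contigs, k = k_align,
                            max_mismatch = max_mismatch)
  focal_f <- filter_3prime(focal_al, ctg$contigs, window = Inf,
                           min_score = 1)
  focal_counts <- count_reads(focal_f$alignments)

  # reference side: reads -> reference-A cDNAs with the 3'-window rule
  ref_al <- align_builtin(ref_lib$reads, sim$refA, k = k_align,
                          max_mismatch = max_mismatch)
  ref_f <- filter_3prime(ref_al, sim$refA, window = window, min_score = 1)
  ref_counts <- count_reads(ref_f$alignments)

  # contig disambiguation across the two references
  cdnas <- c(as_char_seqs(sim$refA), as_char_seqs(sim$refB))
  species <- setNames(rep(c("refA", "refB"),
                          c(length(sim$refA), length(sim$refB))),
                      names(cdnas))
  hits <- hits_builtin(ctg$contigs, cdnas, k = k_hits, species = species)
  assignments <- combine_dual_reference(hits, sim$orthologs,
                                        e_max = e_max, clearance = clearance,
                                        queries = names(ctg$contigs))

  # gene-level focal counts: sum the counts of a gene's assigned contigs
  assigned <- assignments[!is.na(assignments$gene), , drop = FALSE]
  contig_gene <- setNames(assigned$gene, assigned$contig)
  fc <- focal_counts[focal_counts$target %in% names(contig_gene), , drop = FALSE]
  focal_gene <- tapply(fc$count, contig_gene[fc$target], sum)

  genes <- truth$gene
  focal_n <- ifelse(genes %in% names(focal_gene),
                    as.integer(focal_gene[genes]), 0L)
  ref_n <- ifelse(genes %in% ref_counts$target,
                  ref_counts$count[match(genes, ref_counts$target)], 0L)
  counts <- gene_counts(genes, focal_n, ref_n)
  folds <- fold_change_table(counts, pseudocount = pseudocount)

  list(sim = sim, contigs = ctg, assignments = assignments,
       background = background_genes(assignments),
       counts = counts, folds = folds,
       stats = list(focal = focal_f$stats, ref = ref_f$stats),
       truth = truth)
}
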