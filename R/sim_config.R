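#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generator: the
#' size and divergence structure of the three transcriptomes (focal species,
#' annotated reference A, phylogenetically closer reference B), the orthology
#' class mix, contig coverage and fragmentation, the 3'-tag read model, and
#' the differential-expression truth set.
#'
#' Defaults describe the stated world the pipeline is tested against: a
#' mouse-like reference A at 10% nucleotide divergence from the focal species,
#' a guinea-pig-like reference B at 3%, 80% contig coverage, 30% poly-A/T
#' artifact reads and 76 nt single-end tags drawn from the final 1050 nt of
#' each transcript.
#'
#' @param n_genes number of focal-species genes.
#' @param transcript_len_range integer pair, transcript length bounds (nt).
#' @param div_focal_refA per-site substitution probability focal vs
#'   reference A, in `[0, 1]`.
#' @param div_focal_refB per-site substitution probability focal vs
#'   reference B; expected smaller than `div_focal_refA`.
#' @param frac_one_to_one fraction of genes with 1:1 orthology in both
#'   references.
#' @param frac_refB_only fraction resolvable only via reference B (no
#'   reference-A cDNA, but a 1:1 ortholog-table row).
#' @param frac_paralog fraction with a near-duplicate reference-A paralog
#'   (ambiguity source). The remainder `1 - sum` of genes have no reference-A
#'   ortholog at all (cardinality `none`).
#' @param contig_coverage fraction of focal transcripts represented by at
#'   least one contig.
#' @param contig_fragmentation_rate expected number of contig fragments per
#'   covered transcript; `0` means one full-length contig.
#' @param library_size_focal,library_size_ref read counts of the two
#'   libraries.
#' @param read_length tag length in nt (39 or 76 in the study design).
#' @param tag_window nt window at the 3' end of a transcript from which tags
#'   originate (default 1050).
#' @param tag_decay geometric parameter in `(0, 1)` for the positional bias of
#'   tag starts toward the 3' end.
#' @param frac_artifact fraction of reads replaced by poly-A/poly-T junk.
#' @param error_rate per-base sequencing error probability.
#' @param n_de_genes number of differentially expressed genes (default 20%
#'   of `n_genes`).
#' @param de_log2fold_range pair, absolute log2 fold-change bounds for DE
#'   genes (sign drawn at random).
#' @param seed integer seed; identical configs give byte-identical output.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 20, library_size_focal = 1000,
#'                   library_size_ref = 1000)
#' @export
sim_config <- function(n_genes = 200L,
                       transcript_len_range = c(600L, 3000L),
                       div_focal_refA = 0.10,
                       div_focal_refB = 0.03,
                       frac_one_to_one = 0.70,
                       frac_refB_only = 0.10,
                       frac_paralog = 0.10,
                       contig_coverage = 0.80,
                       contig_fragmentation_rate = 1,
                       library_size_focal = 500000L,
                       library_size_ref = 500000L,
                       read_length = 76L,
                       tag_window = 1050L,
                       tag_decay = 0.005,
                       frac_artifact = 0.30,
                       error_rate = 0.005,
                       n_de_genes = round(0.2 * n_genes),
                       de_log2fold_range = c(2, 5),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    transcript_len_range = as.integer(transcript_len_range),
    div_focal_refA = div_focal_refA,
    div_focal_refB = div_focal_refB,
    frac_one_to_one = frac_one_to_one,
    frac_refB_only = frac_refB_only,
    frac_paralog = frac_paralog,
    contig_coverage = contig_coverage,
    contig_fragmentation_rate = contig_fragmentation_rate,
    library_size_focal = as.integer(library_size_focal),
    library_size_ref = as.integer(library_size_ref),
    read_length = as.integer(read_length),
    tag_window = as.integer(tag_window),
    tag_decay = tag_decay,
    frac_artifact = frac_artifact,
    error_rate = error_rate,
    n_de_genes = as.integer(n_de_genes),
    de_log2fold_range = as.numeric(de_log2fold_range),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes >= 1L,
            length(cfg$transcript_len_range) == 2L,
            cfg$transcript_len_range[1] <= cfg$transcript_len_range[2],
            cfg$library_size_focal >= 0L, cfg$library_size_ref >= 0L,
            cfg$read_length >= 1L,
            cfg$n_de_genes >= 0L, cfg$n_de_genes <= cfg$n_genes,
            length(cfg$de_log2fold_range) == 2L,
            cfg$tag_decay > 0, cfg$tag_decay < 1)
  fracs <- c(div_focal_refA = cfg$div_focal_refA,
             div_focal_refB = cfg$div_focal_refB,
             frac_one_to_one = cfg$frac_one_to_one,
             frac_refB_only = cfg$frac_refB_only,
             frac_paralog = cfg$frac_paralog,
             contig_coverage = cfg$contig_coverage,
             frac_artifact = cfg$frac_artifact,
             error_rate = cfg$error_rate)
  bad <- fracs < 0 | fracs > 1
  if (any(bad))
    stop("configuration error: fractions outside [0, 1]: ",
         paste(names(fracs)[bad], collapse = ", "))
  csum <- cfg$frac_one_to_one + cfg$frac_refB_only + cfg$frac_paralog
  if (csum > 1 + 1e-12)
    stop("configuration error: frac_one_to_one + frac_refB_only + ",
         "frac_paralog = ", format(csum), " exceeds 1")
  if (cfg$tag_window < cfg$read_length)
    stop("configuration error: tag_window (", cfg$tag_window,
         ") must be >= read_length (", cfg$read_length, ")")
  if (cfg$transcript_len_range[1] < cfg$read_length)
    stop("configuration error: minimum transcript length must be >= read_length")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_genes, "genes;",
      "div A/B =", x$div_focal_refA, "/", x$div_focal_refB, ";",
      "libraries", x$library_size_focal, "/", x$library_size_ref,
      "x", x$read_length, "nt;",
      "coverage", x$contig_coverage, "; artifacts", x$frac_artifact,
      "; seed", x$seed, "\n")
  invisible(x)
}
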