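#' @name simulate
#' @title Seeded synthetic data with full ground truth
#'
#' @description
#' The generator produces the three transcriptomes the analysis relates
#' (focal species, annotated reference A, closer reference B), a 1:1/1:many
#' orthology table, de novo-like contigs with configurable coverage and
#' fragmentation, and 3'-biased tag reads with poly-A/T artifacts -- together
#' with the truth needed to test every downstream stage: per-gene expression
#' fractions, true log2 fold changes and contig origins.
NULL

random_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

# substitution-only divergence model: each site mutates to one of the three
# other bases with probability `div`
mutate_seq <- function(seq, div) {
  if (div <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  nmut <- rbinom(1L, n, div)
  if (nmut == 0L) return(seq)
  pos <- sample.int(n, nmut)
  alt <- matrix(c("C", "G", "T",  "A", "G", "T",  "A", "C", "T",  "A", "C", "G"),
                nrow = 3L, dimnames = list(NULL, c("A", "C", "G", "T")))
  pick <- sample.int(3L, nmut, replace = TRUE)
  ch[pos] <- alt[cbind(pick, match(ch[pos], colnames(alt)))]
  paste(ch, collapse = "")
}

as_char_seqs <- function(x) {
  if (is(x, "XStringSet")) x <- as.character(x)
  if (!is.character(x) ||
      (length(x) && (is.null(names(x)) || anyNA(names(x)))))
    stop("sequences must be a named character vector or a named DNAStringSet")
  x
}

as_dna_set <- function(x) Biostrings::DNAStringSet(x)

#' Simulate the three related transcriptomes and their orthology table
#'
#' Draws one transcript per focal gene, derives reference-A and reference-B
#' transcripts by independent per-site substitution at the configured
#' divergences, and partitions genes into orthology classes:
#' \describe{
#'   \item{one2one}{present in both references with a 1:1 ortholog-table row.}
#'   \item{refB_only}{no reference-A cDNA; resolvable only through the 1:1
#'     reference-B bridge.}
#'   \item{paralog}{reference A additionally carries a near-duplicate paralog
#'     transcript (`<gene>p`), and the ortholog rows are labelled `one2many`.}
#'   \item{none}{present only in reference B, with cardinality `none` --
#'     contigs from these genes cannot be assigned.}
#' }
#' Baseline expression is log-normal (sd 1.5 on the log2 scale); DE genes are
#' shifted by a uniformly drawn log2 fold with random sign on the focal side.
#'
#' @param config a [sim_config()].
#' @return A list with `refA`, `refB`, `focal` ([Biostrings::DNAStringSet]),
#'   `orthologs` (data.frame: `refB_gene`, `refA_gene`, `cardinality`),
#'   `truth` (per-gene data.frame with expression fractions, classes and true
#'   log2 folds) and the `config`.
#' @examples
#' sim <- simulate_transcriptomes(sim_config(n_genes = 10, seed = 7))
#' names(sim$focal)
#' @export
simulate_transcriptomes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))

  lens <- sample(seq(config$transcript_len_range[1], config$transcript_len_range[2]),
                 n, replace = TRUE)
  focal <- setNames(vapply(lens, random_dna, character(1)), genes)

  # orthology classes (counts rounded, remainder = "none")
  n_one <- round(config$frac_one_to_one * n)
  n_bonly <- round(config$frac_refB_only * n)
  n_par <- round(config$frac_paralog * n)
  if (n_one + n_bonly + n_par > n)
    n_par <- n - n_one - n_bonly
  cls <- sample(rep(c("one2one", "refB_only", "paralog", "none"),
                    c(n_one, n_bonly, n_par, n - n_one - n_bonly - n_par)))
  names(cls) <- genes

  in_refA <- cls %in% c("one2one", "paralog")
  refA <- setNames(vapply(focal[in_refA], mutate_seq, character(1),
                          div = config$div_focal_refA),
                   genes[in_refA])
  # near-duplicate paralogs: a second, independently diverged copy
  par_genes <- genes[cls == "paralog"]
  if (length(par_genes)) {
    par_seqs <- setNames(vapply(focal[par_genes], mutate_seq, character(1),
                                div = config$div_focal_refA),
                         paste0(par_genes, "p"))
    refA <- c(refA, par_seqs)
  }
  refB_ids <- setNames(sub("^g", "gB", genes), genes)
  refB <- setNames(vapply(focal, mutate_seq, character(1),
                          div = config$div_focal_refB),
                   refB_ids)

  orth <- do.call(rbind, lapply(genes, function(g) {
    switch(cls[[g]],
      one2one = ,
      refB_only = data.frame(refB_gene = refB_ids[[g]], refA_gene = g,
                             cardinality = "one2one"),
      paralog = data.frame(refB_gene = refB_ids[[g]],
                           refA_gene = c(g, paste0(g, "p")),
                           cardinality = "one2many"),
      none = data.frame(refB_gene = refB_ids[[g]], refA_gene = NA_character_,
                        cardinality = "none"))
  }))
  rownames(orth) <- NULL

  # expression truth: heavy-tailed baseline, DE shift on the focal side
  base <- 2^rnorm(n, mean = 0, sd = 1.5)
  de_idx <- sample.int(n, config$n_de_genes)
  de_l2f <- numeric(n)
  de_l2f[de_idx] <- runif(config$n_de_genes,
                          config$de_log2fold_range[1],
                          config$de_log2fold_range[2]) *
    sample(c(-1, 1), config$n_de_genes, replace = TRUE)
  focal_w <- base * 2^de_l2f
  ref_w <- ifelse(in_refA, base, 0)   # reference library only covers refA genes
  focal_frac <- focal_w / sum(focal_w)
  ref_frac <- if (sum(ref_w) > 0) ref_w / sum(ref_w) else ref_w

  truth <- data.frame(
    gene = genes,
    class = unname(cls),
    length = lens,
    focal_frac = focal_frac,
    ref_frac = ref_frac,
    is_de = seq_len(n) %in% de_idx,
    de_log2fold = de_l2f,
    true_log2_fold = ifelse(ref_frac > 0, log2(focal_frac / ref_frac), NA_real_)
  )

  list(refA = as_dna_set(refA), refB = as_dna_set(refB),
       focal = as_dna_set(focal), orthologs = orth, truth = truth,
       config = config)
}

#' Simulate de novo-like contigs from the focal transcriptome
#'
#' A fraction `contig_coverage` of transcripts is covered; each covered
#' transcript is cut into a Poisson-distributed number of disjoint substring
#' fragments (at least one; the fragments tile the whole transcript). With
#' `contig_fragmentation_rate = 0` every covered transcript yields exactly one
#' full-length contig.
#'
#' @param focal focal transcriptome (named [Biostrings::DNAStringSet] or
#'   named character vector).
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 1` so transcriptome and
#'   contig draws are independent but jointly reproducible.
#' @param min_contig_len soft minimum fragment length used when placing cut
#'   points (nt).
#' @return A list with `contigs` (a [Biostrings::DNAStringSet]) and `map`, a
#'   data.frame of truth origins (`contig`, `gene`, `start`, `end`; 0-based
#'   half-open).
#' @examples
#' sim <- simulate_transcriptomes(sim_config(n_genes = 5, seed = 3))
#' ctg <- simulate_contigs(sim$focal, sim$config)
#' @export
simulate_contigs <- function(focal, config, seed = config$seed + 1L,
                             min_contig_len = 150L) {
  validate_sim_config(config)
  seqs <- as_char_seqs(focal)
  if (!length(seqs)) stop("focal transcriptome is empty")
  set.seed(seed)
  covered <- runif(length(seqs)) < config$contig_coverage
  out_seq <- character(0)
  map <- list()
  for (i in which(covered)) {
    g <- names(seqs)[i]
    L <- nchar(seqs[[i]])
    rate <- config$contig_fragmentation_rate
    nfrag <- if (rate == 0) 1L else max(1L, rpois(1L, rate))
    nfrag <- min(nfrag, max(1L, L %/% min_contig_len))
    cuts <- if (nfrag > 1L)
      sort(sample(seq(min_contig_len, L - min_contig_len), nfrag - 1L))
    else integer(0)
    bounds <- unique(c(0L, cuts, L))
    for (j in seq_len(length(bounds) - 1L)) {
      id <- sprintf("%s_c%d", g, j)
      s <- bounds[j]; e <- bounds[j + 1L]
      out_seq[id] <- substr(seqs[[i]], s + 1L, e)
      map[[id]] <- data.frame(contig = id, gene = g, start = s, end = e)
    }
  }
  map <- if (length(map)) do.call(rbind, map) else
    data.frame(contig = character(0), gene = character(0),
               start = integer(0), end = integer(0))
  rownames(map) <- NULL
  list(contigs = as_dna_set(out_seq), map = map)
}

# truncated geometric via inverse CDF so truncation does not pile mass at the
# boundary
rgeom_trunc <- function(n, prob, upper) {
  d <- qgeom(runif(n) * pgeom(upper, prob), prob)
  pmin(d, upper)   # guard against qgeom rounding at the edge
}

#' Simulate a 3'-tag read library
#'
#' Draws `library_size` single-end reads: a fraction `frac_artifact` are
#' poly-A or poly-T junk (emulating the oligo-dT tag protocol's artifact
#' reads); the rest are substrings of the source transcripts, multinomial in
#' the supplied expression fractions, with start positions inside the final
#' `tag_window` nt and geometrically biased toward the 3' end (truncated at
#' the transcript start for short transcripts). Per-base substitution errors
#' are applied at `error_rate`; qualities are constant `"I"`.
#'
#' @param seqs source transcripts (named [Biostrings::DNAStringSet] or named
#'   character).
#' @param expression named per-gene expression fractions summing to 1; names
#'   must be a subset of `names(seqs)`.
#' @param config a [sim_config()].
#' @param library_size number of reads (defaults to
#'   `config$library_size_focal`).
#' @param seed RNG seed for this library.
#' @return A list with `reads` (named character vector of read sequences),
#'   `quality` (the constant quality string) and `truth`, a data.frame with
#'   one row per read (`read`, `gene` (`NA` for artifacts), `start`,
#'   `artifact`).
#' @examples
#' sim <- simulate_transcriptomes(sim_config(n_genes = 5, seed = 3))
#' expr <- setNames(sim$truth$focal_frac, sim$truth$gene)
#' lib <- simulate_reads(sim$focal, expr, sim$config, library_size = 100)
#' @export
simulate_reads <- function(seqs, expression, config,
                           library_size = config$library_size_focal,
                           seed = config$seed + 2L) {
  validate_sim_config(config)
  seqs <- as_char_seqs(seqs)
  if (is.null(names(expression)) || !all(names(expression) %in% names(seqs)))
    stop("input error: expression names do not match the supplied sequences")
  if (abs(sum(expression) - 1) > 1e-6)
    stop("input error: expression fractions must sum to 1")
  set.seed(seed)
  n <- as.integer(library_size)
  rl <- config$read_length
  artifact <- runif(n) < config$frac_artifact
  n_tx <- sum(!artifact)

  gene <- rep(NA_character_, n)
  start <- rep(NA_integer_, n)
  reads <- character(n)

  if (n_tx > 0) {
    keep <- expression > 0
    src <- sample(names(expression)[keep], n_tx, replace = TRUE,
                  prob = expression[keep])
    L <- nchar(seqs)[src]
    maxd <- pmin(config$tag_window, L) - rl
    d <- rgeom_trunc(n_tx, config$tag_decay, maxd)
    st <- pmax(L - rl - d, 0L)
    sq <- substring(seqs[src], st + 1L, st + rl)
    # per-base substitution errors
    if (config$error_rate > 0) {
      nerr <- rbinom(n_tx, rl, config$error_rate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(rl, nerr[i])
        for (p in pos) {
          old <- substr(sq[i], p, p)
          substr(sq[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
    }
    gene[!artifact] <- src
    start[!artifact] <- st
    reads[!artifact] <- sq
  }
  if (any(artifact)) {
    polyA <- runif(sum(artifact)) < 0.5
    reads[artifact] <- ifelse(polyA, strrep("A", rl), strrep("T", rl))
  }
  ids <- sprintf("r%07d", seq_len(n))
  names(reads) <- ids
  list(reads = reads,
       quality = strrep("I", rl),
       truth = data.frame(read = ids, gene = gene, start = start,
                          artifact = artifact))
}

#' Draw per-gene read counts directly from the expression truth
#'
#' Convenience for count-level tests and diagnostics: multinomial counts for
#' the focal and reference libraries from the truth table's expression
#' fractions, bypassing read-level simulation. This models the counting
#' outcome of an ideal mapping stage.
#'
#' @param truth the per-gene truth data.frame from
#'   [simulate_transcriptomes()].
#' @param library_size_focal,library_size_ref library sizes.
#' @param seed RNG seed.
#' @return A [gene_counts()] data.frame (`gene`, `focal_76`, `ref_76`).
#' @export
simulate_counts <- function(truth, library_size_focal = 500000L,
                            library_size_ref = 500000L, seed = 1L) {
  set.seed(seed)
  focal <- as.integer(stats::rmultinom(1L, library_size_focal, truth$focal_frac))
  ref <- if (sum(truth$ref_frac) > 0)
    as.integer(stats::rmultinom(1L, library_size_ref, truth$ref_frac))
  else rep(0L, nrow(truth))
  gene_counts(truth$gene, focal, ref)
}
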