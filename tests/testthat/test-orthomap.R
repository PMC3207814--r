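blast_line <- function(q, s, e, bits = 100) {
  paste(q, s, 98.0, 200, 2, 0, 1, 200, 1, 200, format(e), bits, sep = "\t")
}

test_that("load_blast_tab parses the 12-column dialect", {
  p <- tempfile()
  writeLines(c(blast_line("c1", "gA1", 1e-50),
               blast_line("c1", "gB1", "1e-180")), p)
  smap <- c(gA1 = "refA", gB1 = "refB")
  h <- load_blast_tab(p, smap)
  expect_equal(nrow(h), 2L)
  expect_equal(h$evalue[2], 1e-180)
  expect_equal(h$species, c("refA", "refB"))

  writeLines(blast_line("c1", "gX", 0.01), p)
  expect_error(load_blast_tab(p, smap), "gX")
  writeLines("c1\tgA1\tshort", p)
  expect_error(load_blast_tab(p, smap), "line 1")
  writeLines(sub("1e-50", "zzz", blast_line("c1", "gA1", 1e-50)), p)
  expect_error(load_blast_tab(p, smap), "non-numeric")
})

test_that("hits_builtin pseudo-e-values follow the stated formula", {
  set.seed(31)
  cdna1 <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
  cdna2 <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
  cdnas <- c(gA1 = cdna1, gA2 = cdna2)

  # a contig identical to one cDNA dominates every other pair
  h <- hits_builtin(c(c1 = cdna1), cdnas, k = 11)
  best <- h[which.min(h$evalue), ]
  expect_equal(best$subject, "gA1")
  expect_equal(best$evalue, 1e-300)   # floored: 2*500 matched bases

  # doubling the matched bases shrinks the pseudo-e-value as m*n*2^(-2M)
  filler <- function(n) paste(sample(c("A","C"), n, TRUE), collapse = "")
  q <- paste(sample(c("A","C","G","T"), 120, TRUE), collapse = "")
  t_half <- paste0(filler(100), substr(q, 1, 30), filler(100))
  t_full <- paste0(filler(100), substr(q, 1, 60), filler(100))
  tg <- c(t30 = t_half, t60 = t_full)
  hh <- hits_builtin(c(q1 = q), tg, k = 11)
  e30 <- hh$evalue[hh$subject == "t30"]
  e60 <- hh$evalue[hh$subject == "t60"]
  expect_lt(e60, e30)
  n_db <- sum(nchar(tg))
  expect_equal(e30, max(120 * n_db * 2^(-2 * 30), 1e-300), tolerance = 1e-9)
  expect_equal(e60, max(120 * n_db * 2^(-2 * 60), 1e-300), tolerance = 1e-9)

  # disjoint sequences emit no hit
  h0 <- hits_builtin(c(c1 = strrep("AC", 100)), c(g1 = strrep("GT", 100)),
                     k = 11)
  expect_equal(nrow(h0), 0L)
  expect_error(hits_builtin(c(c1 = "ACGT"), c(g1 = "ACGT"), k = 4), ">= 8")
})

hits_for <- function(evalues, genes = paste0("g", seq_along(evalues))) {
  tagdex:::blast_hits(query = rep("c1", length(evalues)), subject = genes,
                      species = "refA", evalue = evalues, bitscore = 50)
}

test_that("classify_contig reproduces the disambiguation rule", {
  expect_equal(classify_contig(hits_for(0.01))$status, "UNIQUE")
  expect_equal(classify_contig(hits_for(c(1e-8, 1e-5)))$status, "CLEAR_BEST")
  expect_equal(classify_contig(hits_for(c(1e-8, 1e-7)))$status, "AMBIGUOUS")
  expect_equal(classify_contig(hits_for(0.2))$status, "NO_SIGNIFICANT_HIT")
  # boundary inclusive: exactly two orders of magnitude
  expect_equal(classify_contig(hits_for(c(1e-6, 1e-4)))$status, "CLEAR_BEST")
  # zero e-value handling
  expect_equal(classify_contig(hits_for(c(0, 1e-50)))$status, "CLEAR_BEST")
  expect_equal(classify_contig(hits_for(c(0, 0)))$status, "AMBIGUOUS")
  # multiple transcripts of one gene collapse before the rule
  h <- tagdex:::blast_hits(rep("c1", 3), c("tx1", "tx2", "tx3"), "refA",
                           c(1e-8, 1e-7, 1e-3), 50)
  gm <- c(tx1 = "g1", tx2 = "g1", tx3 = "g2")
  expect_equal(classify_contig(h, gene_map = gm)$status, "CLEAR_BEST")
  expect_error(classify_contig(rbind(hits_for(0.01),
                                     tagdex:::blast_hits("c2", "g9", "refA",
                                                         0.01, 50))),
               "single query")
})

test_that("classify_contig matches brute-force enumeration on an e-value grid", {
  grid <- c(0, 1e-10, 1e-8, 1e-6, 1e-4, 1e-2, 0.5, 1)
  for (size in 1:3) {
    combos <- do.call(expand.grid, rep(list(grid), size))
    for (i in seq_len(nrow(combos))) {
      ev <- as.numeric(combos[i, ])
      got <- classify_contig(hits_for(ev))$status
      expect_equal(got, brute_force_classify(ev),
                   info = paste("evalues:", paste(ev, collapse = ",")))
    }
  }
})

test_that("raising clearance never rescues an ambiguous call", {
  set.seed(17)
  for (i in 1:200) {
    ev <- 10^(-runif(sample(2:4, 1), 0, 12))
    s1 <- classify_contig(hits_for(ev), clearance = 100)$status
    s2 <- classify_contig(hits_for(ev), clearance = 1000)$status
    if (s1 == "AMBIGUOUS") expect_equal(s2, "AMBIGUOUS")
    if (s2 == "CLEAR_BEST") expect_true(s1 %in% c("CLEAR_BEST"))
  }
})

orth_fixture <- data.frame(
  refB_gene = c("gB1", "gB2", "gB2", "gB3"),
  refA_gene = c("gA1", "gA2", "gA2p", NA),
  cardinality = c("one2one", "one2many", "one2many", "none"))

test_that("dual-reference combination follows the 1:1 bridge", {
  # best hit on a refB gene with a 1:1 refA ortholog: assigned to the ortholog
  h <- tagdex:::blast_hits(rep("c1", 2), c("gB1", "gA9"), c("refB", "refA"),
                           c(1e-30, 1e-5), 50)
  a <- combine_dual_reference(h, orth_fixture)
  expect_equal(a$status, "CLEAR_BEST")
  expect_equal(a$gene, "gA1")

  # best hit on a refB gene with multiple refA orthologs: ORTHOLOGY_FAIL
  h2 <- tagdex:::blast_hits("c2", "gB2", "refB", 1e-40, 50)
  a2 <- combine_dual_reference(h2, orth_fixture)
  expect_equal(a2$status, "ORTHOLOGY_FAIL")
  expect_true(is.na(a2$gene))

  # no refA ortholog at all behaves the same
  h3 <- tagdex:::blast_hits("c3", "gB3", "refB", 1e-40, 50)
  expect_equal(combine_dual_reference(h3, orth_fixture)$status,
               "ORTHOLOGY_FAIL")

  # a refA gene and its own 1:1 refB ortholog are one group => UNIQUE
  h4 <- tagdex:::blast_hits(rep("c4", 2), c("gA1", "gB1"), c("refA", "refB"),
                            c(1e-20, 1e-19), 50)
  a4 <- combine_dual_reference(h4, orth_fixture)
  expect_equal(a4$status, "UNIQUE")
  expect_equal(a4$gene, "gA1")

  # inconsistent cardinality labels are an input error
  bad <- data.frame(refB_gene = "gB9", refA_gene = "gA9",
                    cardinality = "one2many")
  expect_error(combine_dual_reference(h4, bad), "input error")

  # hitless queries appear as NO_SIGNIFICANT_HIT when requested
  a5 <- combine_dual_reference(h4, orth_fixture, queries = c("c4", "c5"))
  expect_equal(a5$status[a5$contig == "c5"], "NO_SIGNIFICANT_HIT")
})

test_that("background set collects distinct assigned genes", {
  asn <- tagdex:::contig_assignment(
    c("c1", "c2", "c3", "c4"),
    c("A", "A", "B", NA),
    c("UNIQUE", "CLEAR_BEST", "UNIQUE", "AMBIGUOUS"))
  expect_equal(background_genes(asn), c("A", "B"))
  empty <- tagdex:::contig_assignment(character(0), character(0), character(0))
  expect_length(background_genes(empty), 0L)
})

test_that("noise-free simulation: background equals the 1:1 set; paralogs ambiguous", {
  cfg <- sim_config(n_genes = 40, transcript_len_range = c(400, 900),
                    div_focal_refA = 0, div_focal_refB = 0,
                    frac_one_to_one = 0.6, frac_refB_only = 0.2,
                    frac_paralog = 0.1, contig_coverage = 1,
                    contig_fragmentation_rate = 0,
                    library_size_focal = 100, library_size_ref = 100,
                    seed = 23)
  sim <- simulate_transcriptomes(cfg)
  ctg <- simulate_contigs(sim$focal, cfg)
  cdnas <- c(as.character(sim$refA), as.character(sim$refB))
  species <- setNames(rep(c("refA", "refB"),
                          c(length(sim$refA), length(sim$refB))),
                      names(cdnas))
  hits <- hits_builtin(ctg$contigs, cdnas, k = 11, species = species)
  asn <- combine_dual_reference(hits, sim$orthologs,
                                queries = names(ctg$contigs))
  cls <- setNames(sim$truth$class, sim$truth$gene)
  one2one_set <- sim$truth$gene[cls %in% c("one2one", "refB_only")]
  expect_setequal(background_genes(asn), one2one_set)
  # every assignment points at the contig's true source gene
  src <- setNames(ctg$map$gene, ctg$map$contig)
  good <- asn[!is.na(asn$gene), ]
  expect_true(all(good$gene == src[good$contig]))
  # with zero divergence every paralog-class contig is ambiguous
  par_contigs <- ctg$map$contig[cls[ctg$map$gene] == "paralog"]
  expect_true(all(asn$status[asn$contig %in% par_contigs] == "AMBIGUOUS"))
})
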