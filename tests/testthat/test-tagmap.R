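write_sam <- function(records, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:t1\tLN:2000", records), path)
  path
}

sam_rec <- function(qname, flag, rname, pos, mapq, seq = "ACGTACGTAC") {
  paste(qname, flag, rname, pos, mapq, paste0(nchar(seq), "M"), "*", 0, 0,
        seq, "*", sep = "\t")
}

test_that("read_sam parses primary records and counts unmapped ones", {
  p <- write_sam(c(sam_rec("r1", 0, "t1", 11, 60),
                   sam_rec("r2", 4, "*", 0, 0)))
  al <- read_sam(p)
  expect_equal(nrow(al), 1L)
  expect_equal(al$read, "r1")
  expect_equal(al$start, 10L)          # POS is 1-based
  expect_equal(al$strand, "+")
  expect_equal(al$score, 60)
  expect_equal(attr(al, "n_unaligned"), 1L)

  # MAPQ 0 is retained here; the score gate filters it later
  al0 <- read_sam(write_sam(sam_rec("r3", 0, "t1", 5, 0)))
  expect_equal(al0$score, 0)

  # reverse strand flag
  alr <- read_sam(write_sam(sam_rec("r4", 16, "t1", 101, 30)))
  expect_equal(alr$strand, "-")
  expect_equal(alr$start, 100L)

  # secondary records are ignored
  als <- read_sam(write_sam(c(sam_rec("r5", 0, "t1", 11, 60),
                              sam_rec("r5", 256, "t1", 99, 0))))
  expect_equal(nrow(als), 1L)
})

test_that("malformed SAM reports the offending line", {
  p <- write_sam(c(sam_rec("r1", 0, "t1", 11, 60), "r2\tbroken"))
  expect_error(read_sam(p), "line 4")
  p2 <- write_sam(sam_rec("r1", 0, "t1", "x", 60))
  expect_error(read_sam(p2), "non-numeric")
})

test_that("built-in aligner places unique substrings exactly", {
  set.seed(7)
  tg <- setNames(vapply(1:3, function(i)
    paste(sample(c("A","C","G","T"), 400, TRUE), collapse = ""),
    character(1)), paste0("t", 1:3))
  rd <- c(r1 = substr(tg[["t2"]], 101, 130))
  al <- align_builtin(rd, tg, k = 10, max_mismatch = 2)
  expect_equal(al$target, "t2")
  expect_equal(al$start, 100L)
  expect_equal(al$score, 30)           # zero mismatches
  expect_equal(al$strand, "+")

  # reverse-complement placement
  rc <- c(r2 = revcomp_chr(substr(tg[["t1"]], 51, 80)))
  alr <- align_builtin(rc, tg, k = 10, max_mismatch = 2)
  expect_equal(alr$target, "t1")
  expect_equal(alr$strand, "-")
  expect_equal(alr$start, 50L)
})

test_that("poly-A reads and foreign reads stay unaligned", {
  set.seed(8)
  tg <- c(t1 = paste(sample(c("C", "G"), 300, TRUE), collapse = ""))
  al <- align_builtin(c(r1 = strrep("A", 39)), tg, k = 10, max_mismatch = 2)
  expect_equal(nrow(al), 0L)
  expect_equal(attr(al, "n_unaligned"), 1L)
  expect_error(align_builtin(c(r1 = strrep("A", 39)), character(0)),
               "empty target")
})

test_that("reads matching identical paralogs are excluded as multimapped", {
  set.seed(9)
  s <- paste(sample(c("A","C","G","T"), 500, TRUE), collapse = "")
  tg <- c(g1 = s, g1p = s)
  rd <- c(r1 = substr(s, 201, 240))
  al <- align_builtin(rd, tg, k = 10, max_mismatch = 2)
  expect_equal(nrow(al), 0L)
  expect_equal(attr(al, "n_multimapped"), 1L)
  expect_equal(brute_force_align(rd[[1]], tg, 2)$status, "multimapped")
})

test_that("built-in aligner agrees with the exhaustive brute-force oracle", {
  # with read length 30, k = 10 and <= 2 mismatches, at least one seed window
  # is intact (pigeonhole), so the seeded search is complete and must agree
  set.seed(21)
  targets <- setNames(vapply(1:10, function(i)
    paste(sample(c("A","C","G","T"), sample(100:300, 1), TRUE),
          collapse = ""), character(1)), sprintf("t%02d", 1:10))
  reads <- character(50)
  for (i in 1:50) {
    src <- sample(names(targets), 1)
    L <- nchar(targets[[src]])
    st <- sample(L - 30, 1)
    r <- substr(targets[[src]], st, st + 29)
    nmut <- sample(0:2, 1)
    if (nmut) for (p in sample(30, nmut))
      substr(r, p, p) <- sample(setdiff(c("A","C","G","T"),
                                        substr(r, p, p)), 1)
    if (runif(1) < 0.3) r <- revcomp_chr(r)
    reads[i] <- r
  }
  names(reads) <- sprintf("r%02d", 1:50)
  al <- align_builtin(reads, targets, k = 10, max_mismatch = 2)
  for (i in seq_along(reads)) {
    oracle <- brute_force_align(reads[[i]], targets, 2)
    row <- al[al$read == names(reads)[i], ]
    if (oracle$status == "aligned") {
      expect_equal(nrow(row), 1L)
      expect_equal(row$target, oracle$target)
      expect_equal(row$start, oracle$start)
      expect_equal(row$score, 30 - oracle$mm)
    } else {
      expect_equal(nrow(row), 0L)
    }
  }
})

test_that("3'-window rule follows the quoted arithmetic", {
  lens <- c(t1 = 2000L, t2 = 800L)
  al <- tagdex:::tag_alignments(
    read = c("a", "b", "c", "d"),
    target = c("t1", "t1", "t2", "t1"),
    start = c(1200L, 100L, 10L, 1500L),
    strand = "+", score = c(60, 60, 60, 0))
  f <- filter_3prime(al, lens, window = 1050)
  # start 1200 >= 2000 - 1050 = 950: retained; start 100: discarded;
  # target shorter than the window: retained whole; score 0: dropped first
  expect_setequal(f$alignments$read, c("a", "c"))
  expect_equal(f$stats$rejected_outside_window, 1L)
  expect_equal(f$stats$rejected_nonpositive_score, 1L)
  expect_equal(f$stats$assigned, 2L)
  expect_equal(f$stats$aligned,
               f$stats$rejected_nonpositive_score +
                 f$stats$rejected_outside_window +
                 f$stats$rejected_multimap + f$stats$assigned)
  # idempotence
  f2 <- filter_3prime(f$alignments, lens, window = 1050)
  expect_identical(as.data.frame(f2$alignments), as.data.frame(f$alignments))
  expect_equal(f2$stats$assigned, f$stats$assigned)
  # unknown target
  expect_error(filter_3prime(al, c(t1 = 2000L), window = 1050), "t2")
})

test_that("count_reads tallies per target", {
  al <- tagdex:::tag_alignments(paste0("r", 1:4), c("T1", "T1", "T1", "T2"),
                                0L, "+", 60)
  ct <- count_reads(al)
  expect_equal(setNames(ct$count, ct$target), c(T1 = 3L, T2 = 1L))
  empty <- count_reads(tagdex:::tag_alignments(character(0), character(0),
                                               integer(0), character(0),
                                               numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("counts equal the simulator truth in a noise-free world", {
  cfg <- sim_config(n_genes = 15, transcript_len_range = c(300, 700),
                    frac_one_to_one = 1, frac_refB_only = 0, frac_paralog = 0,
                    frac_artifact = 0, error_rate = 0, n_de_genes = 0,
                    library_size_focal = 3000, library_size_ref = 100,
                    read_length = 39, seed = 3)
  sim <- simulate_transcriptomes(cfg)
  expr <- setNames(sim$truth$focal_frac, sim$truth$gene)
  lib <- simulate_reads(sim$focal, expr, cfg, library_size = 3000)
  al <- align_builtin(lib$reads, sim$focal, k = 13, max_mismatch = 2)
  ct <- count_reads(filter_3prime(al, sim$focal, window = Inf)$alignments)
  truth_counts <- table(lib$truth$gene)
  expect_equal(setNames(ct$count, ct$target),
               setNames(as.integer(truth_counts), names(truth_counts))[ct$target])
  expect_equal(sum(ct$count), 3000L)
})
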