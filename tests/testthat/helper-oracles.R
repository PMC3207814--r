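# Independent brute-force oracles used across tests. These deliberately
# re-derive results from first principles (exhaustive scans, closed-form
# combinatorics) and never call the code paths they check.

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# exhaustive all-offsets, both-strands scan; returns best placements with
# mismatches <= max_mm
brute_force_align <- function(read, targets, max_mm) {
  placements <- list()
  for (strand in c("+", "-")) {
    rd <- if (strand == "+") read else revcomp_chr(read)
    rch <- strsplit(rd, "")[[1]]
    for (t in names(targets)) {
      tch <- strsplit(targets[[t]], "")[[1]]
      L <- length(tch)
      rl <- length(rch)
      if (L < rl) next
      for (off in 0:(L - rl)) {
        mm <- sum(rch != tch[(off + 1):(off + rl)])
        if (mm <= max_mm)
          placements[[length(placements) + 1L]] <-
            list(target = t, start = off, strand = strand, mm = mm)
      }
    }
  }
  if (!length(placements)) return(list(status = "unaligned"))
  mms <- vapply(placements, `[[`, numeric(1), "mm")
  best <- placements[mms == min(mms)]
  if (length(best) > 1L) return(list(status = "multimapped"))
  c(best[[1]], list(status = "aligned"))
}

# literal restatement of the disambiguation rule, enumerated independently
brute_force_classify <- function(evalues, e_max = 0.05, clearance = 100) {
  ev <- sort(evalues)
  if (length(ev) == 0L || ev[1] >= e_max) return("NO_SIGNIFICANT_HIT")
  if (length(ev) == 1L) return("UNIQUE")
  if (ev[1] == 0 && ev[2] == 0) return("AMBIGUOUS")
  if (ev[1] == 0 || ev[1] * clearance <= ev[2]) return("CLEAR_BEST")
  "AMBIGUOUS"
}

# upper-tail hypergeometric by direct summation of the pmf
brute_force_hyper <- function(x, K, N, n) {
  if (x <= 0) return(1)
  j <- x:min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# per-gene sequence identity between two equal-length transcript sets
pairwise_identity <- function(a, b) {
  vapply(seq_along(a), function(i) {
    x <- strsplit(a[[i]], "")[[1]]
    y <- strsplit(b[[i]], "")[[1]]
    mean(x == y)
  }, numeric(1))
}

curve_points <- function(slope, intercept = 30, conc = c(0, -1, -2, -3)) {
  data.frame(log10_conc = conc, ct = intercept + slope * conc)
}

small_cfg <- function(...) {
  sim_config(n_genes = 20, transcript_len_range = c(300, 800),
             library_size_focal = 2000, library_size_ref = 2000,
             read_length = 39, tag_window = 1050, n_de_genes = 4,
             seed = 11, ...)
}
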