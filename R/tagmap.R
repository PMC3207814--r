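#' @name tagmap
#' @title Tag read placement and 3'-window counting
#' @description Places short tag reads on transcripts or contigs -- either by
#'   ingesting SAM from an external mapper or with a built-in desk-scale
#'   seed-and-extend aligner -- then applies the positive-mapping-score gate
#'   and the 3'-window retention rule before counting reads per target.
NULL

tag_alignments <- function(read, target, start, strand, score,
                           n_unaligned = 0L, n_multimapped = 0L) {
  df <- data.frame(read = read, target = target, start = as.integer(start),
                   strand = strand, score = as.numeric(score))
  attr(df, "n_unaligned") <- as.integer(n_unaligned)
  attr(df, "n_multimapped") <- as.integer(n_multimapped)
  class(df) <- c("tag_alignments", "data.frame")
  df
}

#' @export
print.tag_alignments <- function(x, ...) {
  cat("<tag_alignments>", nrow(x), "alignments;",
      attr(x, "n_unaligned"), "unaligned;",
      attr(x, "n_multimapped"), "multimapped/excluded\n")
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Read primary alignments from a SAM file
#'
#' Parses the mandatory SAM columns of mapped primary records into tag
#' alignments: `POS` is converted to a 0-based start, `MAPQ` becomes the
#' mapping score and FLAG bit 0x10 sets the strand. Unmapped records are
#' counted but not returned; secondary (0x100) and supplementary (0x800)
#' records are ignored.
#'
#' @param path SAM file.
#' @return A `tag_alignments` data.frame (`read`, `target`, `start`,
#'   `strand`, `score`) with attributes `n_unaligned` and `n_secondary`.
#' @examples
#' sam <- tempfile(fileext = ".sam")
#' writeLines(c("@SQ\tSN:t1\tLN:100",
#'              "r1\t0\tt1\t11\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"), sam)
#' read_sam(sam)
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "@"))
  n_unmapped <- 0L
  n_secondary <- 0L
  rows <- vector("list", length(body))
  for (i in seq_along(body)) {
    ln <- body[i]
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L)
      stop("malformed SAM at line ", ln, ": expected >= 11 fields, got ",
           length(f))
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.numeric(f[5]))
    if (is.na(flag) || is.na(pos) || is.na(mapq))
      stop("malformed SAM at line ", ln, ": non-numeric FLAG, POS or MAPQ")
    if (bitwAnd(flag, 0x100L) > 0L || bitwAnd(flag, 0x800L) > 0L) {
      n_secondary <- n_secondary + 1L
      next
    }
    if (bitwAnd(flag, 0x4L) > 0L) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    rows[[i]] <- data.frame(read = f[1], target = f[3], start = pos - 1L,
                            strand = if (bitwAnd(flag, 0x10L) > 0L) "-" else "+",
                            score = mapq)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read = character(0), target = character(0),
               start = integer(0), strand = character(0), score = numeric(0))
  out <- tag_alignments(df$read, df$target, df$start, df$strand, df$score,
                        n_unaligned = n_unmapped)
  attr(out, "n_secondary") <- n_secondary
  out
}

#' Built-in desk-scale tag aligner
#'
#' Exact-k-mer seeded, ungapped extension of each read against every target
#' on both strands. The best placement minimises mismatches; its score is
#' `read length - mismatches`. Reads whose best placement is tied between
#' more than one (target, offset, strand) are multimapped and excluded from
#' the returned alignments (counted in the `n_multimapped` attribute). The
#' result is deterministic in its inputs.
#'
#' @param reads named character vector or [Biostrings::DNAStringSet].
#' @param targets named character vector or [Biostrings::DNAStringSet].
#' @param k seed length; must not exceed the read length.
#' @param max_mismatch maximum mismatches for a valid placement.
#' @param both_strands also try the reverse complement of each read.
#' @return A `tag_alignments` data.frame; attributes `n_unaligned`,
#'   `n_multimapped`.
#' @examples
#' tg <- c(t1 = "ACGTACGTGGATCCAAGCTTACGTACGTAA")
#' align_builtin(c(r1 = "GGATCCAAGCTTACGT"), tg, k = 8)
#' @export
align_builtin <- function(reads, targets, k = 20L, max_mismatch = 4L,
                          both_strands = TRUE) {
  reads <- as_char_seqs(reads)
  targets <- as_char_seqs(targets)
  if (!length(targets)) stop("input error: empty target set")
  if (k > min(nchar(reads)))
    stop("input error: seed length k (", k, ") exceeds the shortest read")
  res <- .align_reads_cpp(unname(reads), unname(targets), as.integer(k),
                          as.integer(max_mismatch), isTRUE(both_strands))
  hit <- res$status == 1L
  tag_alignments(
    read = names(reads)[hit],
    target = names(targets)[res$target[hit]],
    start = res$start[hit],
    strand = res$strand[hit],
    score = nchar(reads[hit]) - res$mismatches[hit],
    n_unaligned = sum(res$status == 0L),
    n_multimapped = sum(res$status == 2L)
  )
}

#' Retain alignments in the 3' window and with positive mapping score
#'
#' Non-positive-score alignments (`score < min_score`) are removed first and
#' tallied separately; a remaining alignment on a target of length `L` is
#' retained iff its start lies in `[max(0, L - window), L)`, i.e. within the
#' final `window` nt of the target. Targets shorter than the window are
#' retained whole. Membership is judged by the alignment start (5'-most
#' aligned base on the target).
#'
#' @param alignments a `tag_alignments` data.frame.
#' @param target_lengths named integer vector of target lengths, or a named
#'   sequence set whose widths are used.
#' @param window window size in nt (default 1050).
#' @param min_score minimum mapping score (default 1, i.e. "positive score").
#' @return A list with `alignments` (retained rows) and `stats`, a
#'   `count_filter_stats` list satisfying
#'   `aligned = rejected_nonpositive_score + rejected_outside_window +
#'   rejected_multimap + assigned`.
#' @export
filter_3prime <- function(alignments, target_lengths, window = 1050L,
                          min_score = 1) {
  if (is(target_lengths, "XStringSet") ||
      (is.character(target_lengths) && !is.null(names(target_lengths)))) {
    target_lengths <- setNames(nchar(as_char_seqs(target_lengths)),
                               names(as_char_seqs(target_lengths)))
  }
  unknown <- setdiff(unique(alignments$target), names(target_lengths))
  if (length(unknown))
    stop("unknown target id(s): ", paste(unknown, collapse = ", "))
  n_multi <- attr(alignments, "n_multimapped")
  if (is.null(n_multi)) n_multi <- 0L
  n_unal <- attr(alignments, "n_unaligned")
  if (is.null(n_unal)) n_unal <- 0L

  pos_ok <- alignments$score >= min_score
  L <- as.numeric(target_lengths[alignments$target])
  in_window <- alignments$start >= pmax(0, L - as.numeric(window)) &
    alignments$start < L
  keep <- pos_ok & in_window
  stats <- count_filter_stats(
    total = nrow(alignments) + n_multi + n_unal,
    aligned = nrow(alignments) + n_multi,
    rejected_nonpositive_score = sum(!pos_ok),
    rejected_outside_window = sum(pos_ok & !in_window),
    rejected_multimap = n_multi,
    assigned = sum(keep)
  )
  out <- alignments[keep, , drop = FALSE]
  attr(out, "n_unaligned") <- n_unal
  attr(out, "n_multimapped") <- 0L   # already accounted in stats
  class(out) <- c("tag_alignments", "data.frame")
  list(alignments = out, stats = stats)
}

count_filter_stats <- function(total, aligned, rejected_nonpositive_score,
                               rejected_outside_window, rejected_multimap,
                               assigned) {
  st <- list(total = total, aligned = aligned,
             rejected_nonpositive_score = rejected_nonpositive_score,
             rejected_outside_window = rejected_outside_window,
             rejected_multimap = rejected_multimap, assigned = assigned)
  if (with(st, aligned != rejected_nonpositive_score +
           rejected_outside_window + rejected_multimap + assigned))
    stop("internal error: filter statistics do not balance")
  structure(st, class = "count_filter_stats")
}

#' @export
print.count_filter_stats <- function(x, ...) {
  cat("<count_filter_stats> total", x$total, "| aligned", x$aligned,
      "| non-positive score", x$rejected_nonpositive_score,
      "| outside 3' window", x$rejected_outside_window,
      "| multimapped", x$rejected_multimap,
      "| assigned", x$assigned, "\n")
  invisible(x)
}

#' Count reads per target
#'
#' @param alignments a (filtered) `tag_alignments` data.frame.
#' @return A data.frame (`target`, `count`); targets with zero alignments
#'   are absent (downstream treats absent as zero).
#' @examples
#' al <- tagdex:::tag_alignments(c("r1", "r2", "r3"), c("t1", "t1", "t2"),
#'                               c(0, 5, 2), "+", 60)
#' count_reads(al)
#' @export
count_reads <- function(alignments) {
  if (!nrow(alignments))
    return(data.frame(target = character(0), count = integer(0)))
  tab <- table(alignments$target)
  df <- data.frame(target = names(tab), count = as.integer(tab))
  df[order(df$target), , drop = FALSE]
}
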