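#' @name enrichment
#' @title Over-representation analysis with the contig-defined background
#' @description Tests whether annotation gene sets are over-represented in a
#'   hit list (e.g. genes over-expressed 5-fold or more) against the
#'   background of genes with at least one unambiguously assigned contig,
#'   using the one-sided hypergeometric upper tail -- optionally in the
#'   conservative EASE variant that removes one gene from the overlap -- and
#'   Benjamini-Hochberg adjustment.
NULL

#' Hypergeometric over-representation test per gene set
#'
#' For each term, the overlap `x` between the hit list (size `n`) and the
#' term's background members (size `K`, after intersecting the set with the
#' background of size `N`) is scored with the upper-tail hypergeometric
#' p-value `P(X >= x)`. With `ease = TRUE` one success is subtracted from
#' the overlap before testing (EASE-style conservative score, the default
#' because annotation-tool outputs the analysis mirrors used it). Terms with
#' zero overlap report p = 1.
#'
#' @param hits character vector of hit gene ids; must be a subset of
#'   `background`.
#' @param background character vector of background gene ids (the universe).
#' @param sets a `gene_set_collection` (see [read_gmt()]) or named list of
#'   character vectors.
#' @param ease subtract one from the overlap before testing (default
#'   `TRUE`).
#' @return An `enrichment` data.frame sorted by p-value: `term`, `name`,
#'   `overlap`, `term_background`, `n_hits`, `n_background`, `pvalue`,
#'   `padj`.
#' @examples
#' sets <- list(T1 = c("a", "b", "c"), T2 = c("d", "e"))
#' enrich(c("a", "b"), c("a", "b", "c", "d", "e", "f"), sets, ease = FALSE)
#' @export
enrich <- function(hits, background, sets, ease = TRUE) {
  hits <- unique(hits)
  background <- unique(background)
  stray <- setdiff(hits, background)
  if (length(stray))
    stop("hit genes absent from background: ", paste(stray, collapse = ", "))
  desc <- attr(sets, "description")
  sets <- lapply(unclass(sets), intersect, background)
  N <- length(background)
  n <- length(hits)
  rows <- lapply(names(sets), function(term) {
    K <- length(sets[[term]])
    x <- length(intersect(sets[[term]], hits))
    x_test <- if (ease) max(x - 1L, 0L) else x
    p <- if (x == 0L) 1 else
      phyper(x_test - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term,
               name = if (!is.null(desc)) unname(desc[term]) else term,
               overlap = x, term_background = K, n_hits = n,
               n_background = N, pvalue = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; the returned
#' vector is in the input order.
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return Adjusted values, `>=` the raw values and `<= 1`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (!m) return(numeric(0))
  ord <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / seq(m, 1) * p[ord]))
  adj[order(ord)]
}
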