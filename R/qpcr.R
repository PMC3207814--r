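#' @name qpcr
#' @title qPCR standard-curve efficiency and delta-Ct relative
#'   quantification
#' @description Cross-platform validation arithmetic: amplification
#'   efficiency from a dilution standard curve with the primer acceptance
#'   gates (efficiency between 1.93 and 2.07, correlation below -0.98),
#'   delta-Ct calibration against a calibrator transcript, relative
#'   abundance `N_rel = E^dCt`, and the matched normalization of sequencing
#'   tag counts to the same calibrator.
NULL

#' Amplification efficiency from a dilution standard curve
#'
#' Fits mean Ct against log10 relative concentration by least squares; for
#' slope `b` the per-cycle amplification factor is `E = 10^(-1/b)` (E = 2 is
#' perfect doubling, slope about -3.32). The primer passes iff
#' `1.93 <= E <= 2.07` and the correlation coefficient of the fit is below
#' `-0.98`.
#'
#' @param series a data.frame with columns `log10_conc` and `ct` (technical
#'   replicates as repeated rows; they are averaged per dilution point).
#' @return A `primer_qc` list: `slope`, `efficiency`, `r`, `pass`,
#'   `n_points`.
#' @examples
#' s <- data.frame(log10_conc = c(0, -1, -2, -3),
#'                 ct = 20 + c(0, 1, 2, 3) / log10(2))
#' efficiency_from_curve(s)   # E = 2, r = -1, pass
#' @export
efficiency_from_curve <- function(series) {
  if (!all(c("log10_conc", "ct") %in% names(series)))
    stop("series must have columns log10_conc, ct")
  mean_ct <- tapply(series$ct, series$log10_conc, mean)
  conc <- as.numeric(names(mean_ct))
  if (length(conc) < 2L || diff(range(conc)) == 0)
    stop("standard curve needs at least two distinct concentrations")
  if (length(conc) < 4L)
    warning("fewer than four dilution points; the study design used >= 4")
  fit <- lm(as.numeric(mean_ct) ~ conc)
  b <- unname(coef(fit)[2])
  if (b == 0) stop("degenerate standard curve: zero slope")
  E <- 10^(-1 / b)
  r <- cor(conc, as.numeric(mean_ct))
  structure(list(slope = b, efficiency = E, r = r,
                 pass = E >= 1.93 && E <= 2.07 && r < -0.98,
                 n_points = length(conc)),
            class = "primer_qc")
}

#' @export
print.primer_qc <- function(x, ...) {
  cat(sprintf("<primer_qc> slope %.4f | E = %.3f | r = %.4f | %s\n",
              x$slope, x$efficiency, x$r, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Relative transcript abundance from mean Ct values
#'
#' `dCt_i = Ct_calibrator - Ct_i` and `N_rel,i = Ebar^dCt_i`, where `Ebar`
#' is the arithmetic mean of the passing primer efficiencies. The calibrator
#' itself has `N_rel = 1`; a more abundant transcript (lower Ct) has
#' `N_rel > 1`. Adding a constant to every mean Ct leaves all `N_rel`
#' unchanged.
#'
#' @param mean_ct named numeric vector of mean Ct values (technical
#'   replicates already averaged).
#' @param calibrator name of the calibrator transcript (must be present).
#' @param efficiencies numeric vector of primer efficiencies (or a list of
#'   `primer_qc` objects); all supplied primers are assumed to have passed
#'   the gates.
#' @return A data.frame: `transcript`, `mean_ct`, `delta_ct`, `n_rel`.
#' @examples
#' relative_abundance(c(Sat2 = 25, A2m = 22), "Sat2", efficiencies = 2)
#' @export
relative_abundance <- function(mean_ct, calibrator, efficiencies) {
  if (is.null(names(mean_ct)) || !(calibrator %in% names(mean_ct)))
    stop("calibrator '", calibrator, "' missing from mean Ct values")
  if (is.list(efficiencies))
    efficiencies <- vapply(efficiencies, function(q) q$efficiency, numeric(1))
  if (any(efficiencies <= 0)) stop("efficiencies must be positive")
  E_bar <- mean(efficiencies)
  d_ct <- mean_ct[[calibrator]] - mean_ct
  data.frame(transcript = names(mean_ct),
             mean_ct = unname(mean_ct),
             delta_ct = unname(d_ct),
             n_rel = unname(E_bar^d_ct))
}

#' Tag counts normalised to a calibrator transcript
#'
#' @param counts named numeric vector of per-transcript read counts.
#' @param calibrator calibrator transcript id; its count must be positive.
#' @return Named numeric vector `count / count[calibrator]`.
#' @examples
#' tag_relative(c(Sat2 = 57, Hprt1 = 249), "Sat2")
#' @export
tag_relative <- function(counts, calibrator) {
  if (is.null(names(counts)) || !(calibrator %in% names(counts)))
    stop("calibrator '", calibrator, "' missing from counts")
  if (counts[[calibrator]] <= 0)
    stop("calibrator count must be positive")
  counts / counts[[calibrator]]
}

#' Side-by-side qPCR and sequencing relative abundances
#'
#' Joins [relative_abundance()] on the qPCR side with [tag_relative()] on
#' the sequencing side for the shared transcripts, both calibrated to the
#' same transcript.
#'
#' @param mean_ct named mean Ct vector.
#' @param counts named tag count vector.
#' @param calibrator shared calibrator id.
#' @param efficiencies primer efficiencies for the mean (see
#'   [relative_abundance()]).
#' @return A data.frame: `transcript`, `n_rel_qpcr`, `n_rel_tags`.
#' @export
qpcr_vs_tags <- function(mean_ct, counts, calibrator, efficiencies) {
  qa <- relative_abundance(mean_ct, calibrator, efficiencies)
  tr <- tag_relative(counts, calibrator)
  shared <- intersect(qa$transcript, names(tr))
  data.frame(transcript = shared,
             n_rel_qpcr = qa$n_rel[match(shared, qa$transcript)],
             n_rel_tags = unname(tr[shared]))
}
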