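#' Target-decoy q-values for PSMs
#'
#' Ranks PSMs by decreasing search score and estimates the false discovery
#' rate at each rank from the decoy counts: `FDR(r) = d(r) / max(1, t(r))`,
#' where `d(r)` and `t(r)` are the numbers of decoy and target PSMs in the
#' top `r`. The q-value of a PSM is the minimum FDR over all ranks at or
#' below its own, which makes the q-values monotone non-decreasing along
#' the ranking. Score ties are broken by placing decoys before targets,
#' the conservative direction.
#'
#' The estimator is the plain decoys/targets ratio; `estimator = "d1t"`
#' selects the `(d + 1)/t` variant for users who prefer the +1 correction.
#'
#' @param psms PSM tibble (see [read_psm_table()]); must contain at least
#'   one target PSM.
#' @param estimator `"dt"` (default, decoys/targets) or `"d1t"`
#'   ((decoys + 1)/targets).
#' @return The input rows sorted by descending score (decoys first on
#'   ties) with two added columns: `fdr` (running FDR at that rank) and
#'   `qvalue` (monotonized).
#' @examples
#' psms <- tibble::tibble(
#'   sample_id = "s1", spectrum_id = paste0("sp", 1:6),
#'   peptide = "PEPTIDEK", proteins = as.list(paste0("P", 1:6)),
#'   score = c(30, 29, 28, 27, 26, 25),
#'   is_decoy = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE)
#' )
#' compute_qvalues(psms)$qvalue
#' @export
compute_qvalues <- function(psms, estimator = c("dt", "d1t")) {
  estimator <- match.arg(estimator)
  stopifnot(is.data.frame(psms), all(c("score", "is_decoy") %in% names(psms)))
  if (nrow(psms) == 0 || all(psms$is_decoy)) {
    abort("q-value estimation needs at least one target PSM")
  }
  ord <- order(-psms$score, !psms$is_decoy)  # ties: decoys first
  out <- psms[ord, , drop = FALSE]
  d <- cumsum(out$is_decoy)
  t <- cumsum(!out$is_decoy)
  num <- if (estimator == "d1t") d + 1 else d
  out$fdr <- num / pmax(1, t)
  out$qvalue <- rev(cummin(rev(out$fdr)))
  out
}

#' Filter PSMs at an FDR threshold
#'
#' Keeps target PSMs whose q-value is at or below `threshold` (0.01 by
#' default, the conventional 1% cut). Decoy PSMs are never returned.
#'
#' @param scored Output of [compute_qvalues()].
#' @param threshold FDR threshold in (0, 1]; 1 keeps every target PSM.
#' @return Tibble of passing target PSMs (same columns as `scored`).
#' @export
filter_at_fdr <- function(scored, threshold = 0.01) {
  stopifnot(is.numeric(threshold), length(threshold) == 1,
            threshold > 0, threshold <= 1)
  if (!"qvalue" %in% names(scored)) {
    abort("`scored` must be the output of compute_qvalues()")
  }
  dplyr::filter(scored, !.data$is_decoy, .data$qvalue <= threshold)
}
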