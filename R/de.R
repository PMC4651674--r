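#' Differential expression by t-tests on Ln(NSpC)
#'
#' Per protein (group), a two-sided two-sample t-test compares the natural
#' log of NSpC between two conditions. The expression ratio is computed on
#' the linear scale as mean(NSpC treatment) / mean(NSpC control) by
#' default (`ratio_mode = "linear"`; `"log"` uses the exponential of the
#' Ln-mean difference instead). A protein is called increased when its
#' ratio exceeds 1 and p <= alpha, decreased when the ratio is below 1 and
#' p <= alpha, and unchanged otherwise. Raw p-values drive the calls, as
#' is conventional for spectral-count studies of this size; a
#' Benjamini-Hochberg column (`bh_fdr`) is always included for users who
#' want multiplicity control.
#'
#' The NSpC matrix must have been built with a positive pseudocount (0.5
#' by default in [run_pipeline()]) so every value is strictly positive and
#' the log is defined; the reproducibility filter only guarantees presence
#' in one of the two conditions.
#'
#' When both groups have zero variance and equal means the test is
#' degenerate and reported as t = 0, p = 1; with unequal means it is
#' reported as t = +/-Inf, p = 0.
#'
#' @param quant NSpC tibble from [compute_nspc()] (strictly positive
#'   values).
#' @param design Design tibble with exactly the two contrasted conditions
#'   (or use `contrast` to name them).
#' @param contrast Character vector `c(treatment, control)` naming the
#'   contrast; required when the design has more than two conditions.
#'   Defaults to the design's second condition versus its first.
#' @param alpha Significance level for the direction calls.
#' @param variant `"student"` (pooled-variance, default) or `"welch"`.
#' @param ratio_mode `"linear"` (ratio of linear means) or `"log"`.
#' @param rows Optional row ids to test (typically the reproducibility
#'   filter's output); default all rows.
#' @return An `spc_de` tibble with one row per protein: `id`,
#'   `mean_nspc_<control>`, `mean_nspc_<treatment>` (names use the actual
#'   condition labels), `ln_mean_<...>`, `ratio`, `t_stat`, `df`,
#'   `p_value`, `bh_fdr`, `direction`. [glance()] gives the DE summary
#'   counts; [autoplot()] draws a volcano plot.
#' @export
de_test <- function(quant, design, contrast = NULL, alpha = 0.05,
                    variant = c("student", "welch"),
                    ratio_mode = c("linear", "log"),
                    rows = quant$id) {
  variant <- match.arg(variant)
  ratio_mode <- match.arg(ratio_mode)
  validate_design(design)
  stopifnot(alpha > 0, alpha <= 1)
  conds <- unique(design$condition)
  if (is.null(contrast)) {
    if (length(conds) != 2) {
      abort("design has more than two conditions; name the contrast as c(treatment, control)")
    }
    contrast <- c(conds[2], conds[1])
  }
  stopifnot(length(contrast) == 2, all(contrast %in% conds))
  trt <- contrast[1]; ctl <- contrast[2]

  q <- quant[quant$id %in% rows, , drop = FALSE]
  trt_cols <- design$sample_id[design$condition == trt]
  ctl_cols <- design$sample_id[design$condition == ctl]
  X <- as.matrix(q[, trt_cols, drop = FALSE])
  Y <- as.matrix(q[, ctl_cols, drop = FALSE])
  if (any(X <= 0) || any(Y <= 0)) {
    abort("NSpC values must be strictly positive for the log transform; rebuild the matrix with a positive pseudocount")
  }

  stats_mat <- vapply(seq_len(nrow(q)), function(i) {
    lnx <- log(X[i, ]); lny <- log(Y[i, ])
    if (var(lnx) == 0 && var(lny) == 0) {
      # degenerate: no within-group variability
      df <- length(lnx) + length(lny) - 2
      if (mean(lnx) == mean(lny)) c(0, df, 1)
      else c(sign(mean(lnx) - mean(lny)) * Inf, df, 0)
    } else {
      tt <- t.test(lnx, lny, var.equal = (variant == "student"))
      c(unname(tt$statistic), unname(tt$parameter), tt$p.value)
    }
  }, numeric(3))
  res <- tibble(t_stat = stats_mat[1, ], df = stats_mat[2, ],
                p_value = stats_mat[3, ])

  mean_trt <- rowMeans(X); mean_ctl <- rowMeans(Y)
  ratio <- if (ratio_mode == "linear") mean_trt / mean_ctl
           else exp(rowMeans(log(X)) - rowMeans(log(Y)))

  out <- tibble(id = q$id)
  out[[paste0("mean_nspc_", ctl)]] <- mean_ctl
  out[[paste0("mean_nspc_", trt)]] <- mean_trt
  out[[paste0("ln_mean_", ctl)]] <- rowMeans(log(Y))
  out[[paste0("ln_mean_", trt)]] <- rowMeans(log(X))
  out$ratio <- ratio
  out <- dplyr::bind_cols(out, res)
  out$bh_fdr <- p.adjust(out$p_value, method = "BH")
  out$direction <- dplyr::case_when(
    out$p_value <= alpha & out$ratio > 1 ~ "increased",
    out$p_value <= alpha & out$ratio < 1 ~ "decreased",
    .default = "unchanged"
  )
  degenerate <- sum(res$p_value == 1 & res$t_stat == 0)
  if (degenerate > 0) {
    inform(paste0(degenerate, " protein(s) had zero variance in both groups; ",
                  "reported as t = 0, p = 1"))
  }
  structure(out,
            class = c("spc_de", class(tibble())),
            alpha = alpha, contrast = c(treatment = trt, control = ctl),
            variant = variant, ratio_mode = ratio_mode)
}

#' Summarize differential-expression calls
#'
#' @param results An `spc_de` tibble from [de_test()].
#' @param alpha Significance level; defaults to the one used in
#'   [de_test()].
#' @return A one-row tibble: `n_tested`, `n_de`, `n_increased`,
#'   `n_decreased`.
#' @export
summarize_de <- function(results, alpha = attr(results, "alpha") %||% 0.05) {
  sig <- results$p_value <= alpha
  tibble(
    n_tested = nrow(results),
    n_de = sum(sig),
    n_increased = sum(sig & results$ratio > 1),
    n_decreased = sum(sig & results$ratio < 1)
  )
}

#' @method glance spc_de
#' @export
glance.spc_de <- function(x, ...) summarize_de(x)

#' @method tidy spc_de
#' @export
tidy.spc_de <- function(x, ...) {
  out <- x
  class(out) <- class(tibble())
  out
}
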