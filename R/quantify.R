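#' Normalized spectral counts (NSpC / NSAF)
#'
#' For protein \eqn{k} in one sample,
#' \deqn{NSpC_k = \frac{SpC_k / L_k}{\sum_{i=1}^{n} SpC_i / L_i}}
#' where \eqn{SpC_k} is the spectral count, \eqn{L_k} the protein (group)
#' length in residues, and the sum runs over all \eqn{n} rows of the
#' supplied matrix. Each sample column of the result sums to 1. An
#' optional pseudocount is added to every count before normalization so
#' that downstream log transforms are defined for proteins missing from a
#' sample; with the default `pseudocount = 0`, rows with zero counts get
#' NSpC 0.
#'
#' @param counts Count tibble (`id` plus one integer column per sample),
#'   as from [spectral_count_matrix()].
#' @param lengths Either a named numeric vector mapping row ids to lengths
#'   or a tibble/data frame with `id`-like and `length` columns (the
#'   output of [group_proteins()] works). Every row id needs a length.
#' @param pseudocount Non-negative count added to every cell before
#'   normalization.
#' @return A tibble `id`, `length`, then one NSpC column per sample.
#' @examples
#' counts <- tibble::tibble(id = c("A", "B"), s1 = c(10L, 10L))
#' compute_nspc(counts, c(A = 100, B = 200))  # 2/3 and 1/3
#' @export
compute_nspc <- function(counts, lengths, pseudocount = 0) {
  stopifnot(is.data.frame(counts), "id" %in% names(counts),
            is.numeric(pseudocount), length(pseudocount) == 1, pseudocount >= 0)
  lengths <- as_length_map(lengths)
  missing <- setdiff(counts$id, names(lengths))
  if (length(missing) > 0) {
    abort(paste0("no length for row id(s): ", paste(missing, collapse = ", ")))
  }
  L <- unname(lengths[counts$id])
  stopifnot(all(L > 0))
  samples <- setdiff(names(counts), "id")
  out <- tibble(id = counts$id, length = L)
  for (s in samples) {
    w <- (counts[[s]] + pseudocount) / L
    denom <- sum(w)
    if (denom == 0) {
      abort(paste0("sample ", s, " has all-zero counts and pseudocount 0; ",
                   "NSpC is undefined"))
    }
    out[[s]] <- w / denom
  }
  out
}

as_length_map <- function(lengths) {
  if (is.data.frame(lengths)) {
    idcol <- intersect(c("id", "group_id", "accession"), names(lengths))[1]
    if (is.na(idcol) || !"length" %in% names(lengths)) {
      abort("`lengths` data frame needs a `length` column and one of id/group_id/accession")
    }
    setNames(as.numeric(lengths$length), lengths[[idcol]])
  } else if (is.numeric(lengths) && !is.null(names(lengths))) {
    lengths
  } else {
    abort("`lengths` must be a named numeric vector or a data frame")
  }
}

#' Replicate reproducibility filter
#'
#' Keeps a protein (group) iff there is at least one condition in which
#' every replicate has a spectral count of at least `min_spc` — i.e. the
#' protein was seen consistently, with some minimum evidence, in all
#' replicates of the control or of the treatment arm.
#'
#' @param counts Count tibble (`id` plus sample columns).
#' @param design Design tibble (`sample_id`, `condition`).
#' @param min_spc Minimum spectral count required in every replicate of a
#'   qualifying condition (>= 1).
#' @return Character vector of row ids passing the filter, in input order.
#' @export
reproducibility_filter <- function(counts, design, min_spc = 2) {
  validate_design(design)
  stopifnot(min_spc >= 1)
  stopifnot(all(design$sample_id %in% names(counts)))
  keep <- rep(FALSE, nrow(counts))
  for (cond in unique(design$condition)) {
    cols <- design$sample_id[design$condition == cond]
    m <- as.matrix(counts[, cols, drop = FALSE])
    keep <- keep | apply(m >= min_spc, 1, all)
  }
  counts$id[keep]
}

#' Replicate concordance (R-squared)
#'
#' For every within-condition pair of replicate samples, computes the
#' squared Pearson correlation of their NSpC vectors over the selected
#' rows, on the linear NSpC scale, and averages over all pairs.
#'
#' @param quant NSpC tibble from [compute_nspc()].
#' @param design Design tibble; each condition needs >= 2 replicates.
#' @param rows Row ids to correlate over (typically the output of
#'   [reproducibility_filter()]); default all rows.
#' @return An object of class `spc_r2`: use [tidy()] for the per-pair
#'   table (`condition`, `sample_1`, `sample_2`, `r_squared`) and
#'   [glance()] for the one-row summary (`mean_r_squared`, `n_pairs`,
#'   `n_rows`). Pairs involving a zero-variance column are dropped with a
#'   warning.
#' @export
replicate_r2 <- function(quant, design, rows = quant$id) {
  validate_design(design)
  q <- quant[quant$id %in% rows, , drop = FALSE]
  if (nrow(q) < 2) abort("need >= 2 rows to compute correlations")
  pairs <- purrr::map(unique(design$condition), function(cond) {
    s <- design$sample_id[design$condition == cond]
    cmb <- utils::combn(s, 2)
    tibble(condition = cond, sample_1 = cmb[1, ], sample_2 = cmb[2, ])
  }) %>% bind_rows()
  r2 <- purrr::map2_dbl(pairs$sample_1, pairs$sample_2, function(a, b) {
    x <- q[[a]]; y <- q[[b]]
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y)^2
  })
  if (anyNA(r2)) {
    warn(paste0(sum(is.na(r2)), " replicate pair(s) had a zero-variance ",
                "column; excluded from the mean"))
  }
  pairs$r_squared <- r2
  structure(list(pairs = pairs, n_rows = nrow(q)), class = "spc_r2")
}

#' @method tidy spc_r2
#' @export
tidy.spc_r2 <- function(x, ...) x$pairs

#' @method glance spc_r2
#' @export
glance.spc_r2 <- function(x, ...) {
  tibble(
    mean_r_squared = mean(x$pairs$r_squared, na.rm = TRUE),
    n_pairs = sum(!is.na(x$pairs$r_squared)),
    n_rows = x$n_rows
  )
}

#' @export
print.spc_r2 <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Replicate concordance over %d proteins: mean R^2 = %.3f (%d pairs)\n",
              g$n_rows, g$mean_r_squared, g$n_pairs))
  print(x$pairs)
  invisible(x)
}
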