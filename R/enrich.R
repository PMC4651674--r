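#' GO term enrichment (singular enrichment analysis)
#'
#' Tests a query protein list for over-represented GO terms against a
#' background set, one term at a time, with the one-sided hypergeometric
#' upper-tail test (equivalently a one-sided Fisher exact test):
#' the p-value is the probability of drawing at least the observed number
#' of term-annotated proteins when `|query|` proteins are drawn without
#' replacement from the background. Benjamini-Hochberg FDR is computed
#' across all tested terms.
#'
#' Annotations are assumed to be pre-propagated to ancestor terms by the
#' provider; no GO DAG traversal is performed here. By default the
#' effective background is restricted to accessions carrying at least one
#' annotation, the usual enrichment-server convention; set
#' `include_unannotated = TRUE` to keep unannotated proteins in the urn.
#'
#' @param query_ids Character vector of query accessions; must be a
#'   subset of `background_ids`.
#' @param annotations Annotation tibble from [read_go_annotations()].
#' @param background_ids Character vector of background accessions.
#' @param min_term_size Minimum number of background proteins a term must
#'   annotate to be tested.
#' @param include_unannotated Keep proteins without any annotation in the
#'   background universe.
#' @return A tibble sorted by ascending p-value: `term_id`, `ontology`,
#'   `description`, `n_input`, `n_background`, `p_value`, `fdr`.
#' @export
enrich_go <- function(query_ids, annotations, background_ids,
                      min_term_size = 5, include_unannotated = FALSE) {
  query_ids <- unique(query_ids)
  background_ids <- unique(background_ids)
  offenders <- setdiff(query_ids, background_ids)
  if (length(offenders) > 0) {
    abort(paste0("query id(s) not in the background: ",
                 paste(head(offenders, 10), collapse = ", ")))
  }
  ann <- annotations %>% filter(.data$accession %in% background_ids)
  universe <- if (include_unannotated) background_ids else unique(ann$accession)
  query <- intersect(query_ids, universe)
  N <- length(universe)
  n_draw <- length(query)

  per_term <- ann %>%
    distinct(.data$term_id, .data$ontology, .data$description, .data$accession) %>%
    group_by(.data$term_id, .data$ontology, .data$description) %>%
    summarise(
      n_background = dplyr::n_distinct(.data$accession),
      n_input = sum(.data$accession %in% query),
      .groups = "drop"
    ) %>%
    filter(.data$n_background >= min_term_size)

  per_term %>%
    mutate(p_value = phyper(.data$n_input - 1, .data$n_background,
                            N - .data$n_background, n_draw,
                            lower.tail = FALSE),
           fdr = p.adjust(.data$p_value, method = "BH")) %>%
    arrange(.data$p_value, .data$term_id)
}
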