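#' Pipeline configuration
#'
#' Bundles input paths (or in-memory tables), thresholds and switches for
#' [run_pipeline()]. All thresholds default to the conventional values of
#' spectral-count studies: PSM FDR 0.01, at least 2 spectral counts in
#' every replicate of one condition, t-test alpha 0.05, pseudocount 0.5
#' for the DE-stage normalization.
#'
#' @param psms PSM tibble, or character vector of PSM TSV paths.
#' @param proteins Protein tibble from [read_fasta()], or a FASTA path.
#' @param design Design tibble, or a YAML design path.
#' @param annotations Optional GO annotation tibble or TSV path; the
#'   enrichment stage is skipped when absent.
#' @param outdir Optional output directory for stage TSVs and the run
#'   manifest; nothing is written when `NULL`.
#' @param fdr_threshold PSM q-value cut.
#' @param min_spc Reproducibility filter threshold.
#' @param alpha DE significance level.
#' @param pseudocount Count offset for the DE-stage NSpC.
#' @param decoy_prefix Decoy accession prefix.
#' @param variant t-test variant, `"student"` or `"welch"`.
#' @param ratio_mode `"linear"` or `"log"` expression ratios.
#' @param quantify_by `"group"` (default) quantifies protein groups with
#'   the representative's length; `"accession"` quantifies every
#'   accession separately.
#' @param contrast Optional `c(treatment, control)` pair.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(psms, proteins, design, annotations = NULL,
                            outdir = NULL,
                            fdr_threshold = 0.01, min_spc = 2,
                            alpha = 0.05, pseudocount = 0.5,
                            decoy_prefix = "rev_",
                            variant = c("student", "welch"),
                            ratio_mode = c("linear", "log"),
                            quantify_by = c("group", "accession"),
                            contrast = NULL) {
  variant <- match.arg(variant)
  ratio_mode <- match.arg(ratio_mode)
  quantify_by <- match.arg(quantify_by)
  stopifnot(fdr_threshold > 0, fdr_threshold < 1, min_spc >= 1,
            alpha > 0, alpha <= 1, pseudocount >= 0)
  structure(as.list(environment()), class = "pipeline_config")
}

resolve_input <- function(x, reader, bind = FALSE) {
  if (is.character(x)) {
    if (bind && length(x) > 1) bind_rows(lapply(x, reader)) else reader(x)
  } else {
    x
  }
}

#' Run the full spectral-counting pipeline
#'
#' Executes the analysis chain end to end: target-decoy q-values and FDR
#' filtering of PSMs, protein grouping, spectral counting, the replicate
#' reproducibility filter, NSpC normalization of the filtered matrix,
#' replicate concordance, differential expression with expression
#' ratios, GO enrichment of the DE set (when annotations are supplied)
#' and a physico-chemical profile of identified versus database
#' proteins. The run is deterministic: identical inputs and
#' configuration reproduce identical outputs.
#'
#' @param config A [pipeline_config()] object.
#' @return An `spcquant_run` list with elements `scored`, `psms_filtered`,
#'   `groups`, `counts`, `kept_ids`, `quant`, `r2`, `de`, `enrichment`
#'   (or `NULL`), `physchem`, and `manifest` (named list of stage counts
#'   and parameters). When `config$outdir` is set, stage TSVs and
#'   `manifest.json` are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  psms <- resolve_input(config$psms, function(p) read_psm_table(p, config$decoy_prefix),
                        bind = TRUE)
  proteins <- resolve_input(config$proteins, read_fasta)
  design <- resolve_input(config$design, read_design)
  annotations <- if (!is.null(config$annotations)) {
    resolve_input(config$annotations, read_go_annotations)
  }
  validate_design(design)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  scored <- stage("fdr", compute_qvalues(psms))
  kept_psms <- stage("fdr", filter_at_fdr(scored, config$fdr_threshold))

  groups <- stage("group", {
    g <- group_proteins(kept_psms, proteins)
    if (config$quantify_by == "accession") explode_groups(g, proteins) else g
  })
  counts <- stage("count", spectral_count_matrix(kept_psms, groups, design))
  kept_ids <- stage("filter",
                    reproducibility_filter(counts, design, config$min_spc))
  counts_f <- counts[counts$id %in% kept_ids, , drop = FALSE]
  lengths_map <- setNames(groups$length, groups$group_id)
  quant <- stage("nspc",
                 compute_nspc(counts_f, lengths_map, config$pseudocount))
  r2 <- stage("r2", replicate_r2(quant, design))
  de <- stage("de", de_test(quant, design, contrast = config$contrast,
                            alpha = config$alpha, variant = config$variant,
                            ratio_mode = config$ratio_mode))

  enrichment <- NULL
  if (!is.null(annotations)) {
    de_groups <- de$id[de$p_value <= config$alpha]
    query <- groups$representative[match(de_groups, groups$group_id)]
    background <- groups$representative
    enrichment <- stage("enrich",
                        enrich_go(query, annotations, background))
  }

  identified <- unique(unlist(groups$members))
  physchem <- stage("physchem", physchem_profile(proteins, identified))

  de_summary <- summarize_de(de)
  manifest <- list(
    parameters = config[c("fdr_threshold", "min_spc", "alpha", "pseudocount",
                          "decoy_prefix", "variant", "ratio_mode",
                          "quantify_by")],
    n_psms_in = nrow(psms),
    n_decoys_seen = sum(psms$is_decoy),
    n_psms_fdr = nrow(kept_psms),
    n_groups = nrow(groups),
    n_accessions_identified = length(identified),
    n_filtered = length(kept_ids),
    n_tested = de_summary$n_tested,
    n_de = de_summary$n_de,
    n_increased = de_summary$n_increased,
    n_decreased = de_summary$n_decreased,
    mean_r2 = glance(r2)$mean_r_squared
  )
  inform(sprintf(
    "PSMs %d -> %d at FDR %.3g; %d groups; %d reproducible; %d DE (%d up, %d down); mean R^2 %.3f",
    manifest$n_psms_in, manifest$n_psms_fdr, config$fdr_threshold,
    manifest$n_groups, manifest$n_filtered, manifest$n_de,
    manifest$n_increased, manifest$n_decreased, manifest$mean_r2))

  run <- structure(
    list(scored = scored, psms_filtered = kept_psms, groups = groups,
         counts = counts, kept_ids = kept_ids, quant = quant, r2 = r2,
         de = de, enrichment = enrichment, physchem = physchem,
         manifest = manifest),
    class = "spcquant_run")

  if (!is.null(config$outdir)) write_run(run, config$outdir)
  run
}

explode_groups <- function(groups, proteins) {
  accs <- unique(unlist(groups$members))
  tibble(
    group_id = accs,
    representative = accs,
    members = as.list(accs),
    n_members = 1L,
    peptides = list(character()),
    n_peptides = NA_integer_,
    length = as.integer(proteins$length[match(accs, proteins$accession)])
  ) %>% arrange(.data$group_id)
}

write_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_psm_table(run$psms_filtered[, c("sample_id", "spectrum_id", "peptide",
                                        "proteins", "score", "is_decoy")],
                  file.path(outdir, "filtered_psms.tsv"))
  groups_flat <- run$groups %>%
    mutate(members = vapply(.data$members, paste, character(1), collapse = ";")) %>%
    select("group_id", "representative", "members", "n_members",
           "n_peptides", "length")
  readr::write_tsv(groups_flat, file.path(outdir, "groups.tsv"))
  readr::write_tsv(run$counts, file.path(outdir, "counts.tsv"))
  readr::write_tsv(run$quant, file.path(outdir, "nspc.tsv"))
  readr::write_tsv(tidy(run$r2), file.path(outdir, "r2.tsv"))
  readr::write_tsv(tidy(run$de), file.path(outdir, "de.tsv"))
  if (!is.null(run$enrichment)) {
    readr::write_tsv(run$enrichment, file.path(outdir, "enrichment.tsv"))
  }
  readr::write_tsv(run$physchem %>% select(-"sequence"),
                   file.path(outdir, "physchem.tsv"))
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.spcquant_run <- function(x, ...) {
  m <- x$manifest
  cat("spcquant pipeline run\n")
  cat(sprintf("  PSMs: %d in, %d decoys, %d pass FDR %.3g\n",
              m$n_psms_in, m$n_decoys_seen, m$n_psms_fdr,
              m$parameters$fdr_threshold))
  cat(sprintf("  Proteins: %d groups (%d accessions), %d reproducible\n",
              m$n_groups, m$n_accessions_identified, m$n_filtered))
  cat(sprintf("  DE: %d of %d (alpha %.3g): %d increased, %d decreased\n",
              m$n_de, m$n_tested, m$parameters$alpha, m$n_increased,
              m$n_decreased))
  cat(sprintf("  Replicate concordance: mean R^2 = %.3f\n", m$mean_r2))
  invisible(x)
}

#' Filter, normalize and test a ready-made count table
#'
#' Convenience wrapper for count tables that did not come from PSMs (for
#' example per-protein spectral counts exported from another tool):
#' applies the reproducibility filter, NSpC normalization with a
#' pseudocount, replicate concordance and the Ln t-test with expression
#' ratios, and returns all intermediate results.
#'
#' @param counts Tibble `id` + one integer column per sample.
#' @param lengths Named vector or data frame of protein lengths.
#' @param design Design tibble (`sample_id`, `condition`).
#' @inheritParams pipeline_config
#' @return A list: `kept_ids`, `quant`, `r2`, `de`, `summary`.
#' @export
reproduce_from_counts <- function(counts, lengths, design,
                                  min_spc = 2, alpha = 0.05,
                                  pseudocount = 0.5,
                                  variant = c("student", "welch"),
                                  ratio_mode = c("linear", "log"),
                                  contrast = NULL) {
  variant <- match.arg(variant)
  ratio_mode <- match.arg(ratio_mode)
  kept_ids <- reproducibility_filter(counts, design, min_spc)
  counts_f <- counts[counts$id %in% kept_ids, , drop = FALSE]
  quant <- compute_nspc(counts_f, lengths, pseudocount)
  r2 <- replicate_r2(quant, design)
  de <- de_test(quant, design, contrast = contrast, alpha = alpha,
                variant = variant, ratio_mode = ratio_mode)
  list(kept_ids = kept_ids, quant = quant, r2 = r2, de = de,
       summary = summarize_de(de))
}
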