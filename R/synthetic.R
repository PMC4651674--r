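# Rough eukaryotic amino-acid background frequencies used to draw
# synthetic protein sequences (order follows STANDARD_AA).
AA_FREQS <- c(
  A = 0.083, C = 0.014, D = 0.055, E = 0.067, F = 0.039, G = 0.071,
  H = 0.023, I = 0.059, K = 0.058, L = 0.097, M = 0.024, N = 0.041,
  P = 0.047, Q = 0.040, R = 0.055, S = 0.066, T = 0.053, V = 0.069,
  W = 0.011, Y = 0.029
)

#' Parameters for the synthetic experiment generator
#'
#' The defaults emulate the structure of a shotgun proteomics comparison
#' of two conditions with three biological replicates each: ~2,000
#' proteins with lengths drawn log-uniformly over 60-3,000 residues,
#' log-normal(0, 1) abundances, an expected 30,000 correct peptide-
#' spectrum matches per sample whose per-protein expectation scales with
#' abundance x length, a 5% spiked truly-differential subset at 8-fold
#' change, 10% of peptides shared between two parent proteins, and a
#' two-component score model (correct matches ~ Normal(30, 5), incorrect
#' and decoy matches ~ Normal(15, 5)) with 10% incorrect target PSMs.
#'
#' @param n_proteins Number of target proteins in the database.
#' @param length_range Two-vector; protein lengths are log-uniform over
#'   this range (residues).
#' @param n_replicates Biological replicates per condition (>= 2).
#' @param conditions Names of the two conditions, `c(control, treatment)`.
#' @param depth Expected number of correct target PSMs per sample.
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance model.
#' @param de_fraction Fraction of proteins that are truly differential.
#' @param fold_change Fold change applied to spiked proteins (> 0);
#'   direction (up/down in treatment) is split evenly at random.
#' @param shared_peptide_fraction Fraction of observable peptides carried
#'   by two parent proteins.
#' @param incorrect_target_fraction Expected incorrect target PSMs as a
#'   fraction of `depth`; the same expected number of decoy PSMs is
#'   generated, the neutral choice under which decoy counts estimate
#'   incorrect-target counts without bias.
#' @param target_score_mean,target_score_sd Score model for correct PSMs.
#' @param decoy_score_mean,decoy_score_sd Score model for incorrect and
#'   decoy PSMs.
#' @param dispersion Negative-binomial over-dispersion of counts; 0 means
#'   Poisson.
#' @param decoy_prefix Accession prefix for decoy PSMs.
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical output.
#' @return A `synth_params` list.
#' @export
synth_params <- function(n_proteins = 2000,
                         length_range = c(60, 3000),
                         n_replicates = 3,
                         conditions = c("control", "treatment"),
                         depth = 30000,
                         abundance_meanlog = 0,
                         abundance_sdlog = 1,
                         de_fraction = 0.05,
                         fold_change = 8,
                         shared_peptide_fraction = 0.1,
                         incorrect_target_fraction = 0.1,
                         target_score_mean = 30, target_score_sd = 5,
                         decoy_score_mean = 15, decoy_score_sd = 5,
                         dispersion = 0,
                         decoy_prefix = "rev_",
                         seed = 1) {
  stopifnot(n_proteins >= 2, length(length_range) == 2,
            length_range[1] >= 10, length_range[2] > length_range[1],
            n_replicates >= 2, length(conditions) == 2,
            depth > 0, de_fraction >= 0, de_fraction <= 1,
            fold_change > 0,
            shared_peptide_fraction >= 0, shared_peptide_fraction <= 1,
            incorrect_target_fraction >= 0, incorrect_target_fraction <= 1,
            dispersion >= 0)
  structure(as.list(environment()), class = "synth_params")
}

# tryptic-like digest: cleave after K/R, keep observable-size fragments;
# guarantees at least one peptide per protein
digest_sequence <- function(sequence, min_len = 6, max_len = 30) {
  frags <- strsplit(gsub("([KR])", "\\1\x01", sequence), "\x01",
                    fixed = TRUE)[[1]]
  keep <- frags[nchar(frags) >= min_len & nchar(frags) <= max_len]
  if (length(keep) == 0) {
    keep <- substr(sequence, 1, min(nchar(sequence), max_len))
  }
  unique(keep)
}

#' Generate a synthetic shotgun-proteomics experiment
#'
#' Draws a protein database, per-condition abundances with a spiked
#' truly-differential subset, integer spectral counts (Poisson by
#' default, expectation proportional to abundance x length and scaled to
#' the target depth), and expands the counts into PSM rows with
#' tryptic-like peptides. A fraction of peptides is attributed to two
#' parent proteins; incorrect target PSMs and reversed-accession decoy
#' PSMs are appended with low scores. GO annotations are drawn so that a
#' designated term (`GO:0000001`, "synthetic heat response") is enriched
#' in the truly-differential set.
#'
#' @param params A [synth_params()] object.
#' @param outdir Optional directory; when given, the PSM table, FASTA
#'   database, GO annotation table, design YAML and truth tables are
#'   written there as plain text.
#' @return A list: `psms` (canonical PSM tibble), `proteins` (database
#'   tibble as from [read_fasta()]), `annotations`, `design`, and `truth`
#'   (list with `proteins` — accession, length, per-condition abundance,
#'   `is_de`, `direction` — and `psm_labels` — sample_id, spectrum_id,
#'   `correct`), plus `params`.
#' @export
generate_experiment <- function(params = synth_params(), outdir = NULL) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  p <- params
  n <- p$n_proteins

  # protein database
  accession <- sprintf("SYN%05d", seq_len(n))
  len <- round(exp(runif(n, log(p$length_range[1]), log(p$length_range[2]))))
  sequence <- vapply(len, function(L) {
    paste(sample(STANDARD_AA, L, replace = TRUE, prob = AA_FREQS),
          collapse = "")
  }, character(1))
  proteins <- tibble(accession = accession,
                     description = "synthetic protein",
                     sequence = sequence, length = nchar(sequence))

  # observable peptide catalog, with a shared fraction given a second parent
  catalogs <- lapply(sequence, digest_sequence)
  pep_tbl <- tibble(
    owner = rep(seq_len(n), lengths(catalogs)),
    peptide = unlist(catalogs)
  )
  n_shared <- floor(p$shared_peptide_fraction * nrow(pep_tbl))
  partner <- rep(NA_integer_, nrow(pep_tbl))
  if (n_shared > 0) {
    idx <- sample(nrow(pep_tbl), n_shared)
    # uniform over the n-1 non-owner proteins
    draw <- sample.int(n - 1, n_shared, replace = TRUE)
    partner[idx] <- draw + (draw >= pep_tbl$owner[idx])
  }
  pep_tbl$partner <- partner
  cat_index <- split(seq_len(nrow(pep_tbl)), pep_tbl$owner)

  # abundances and spiked differential subset
  abundance <- rlnorm(n, p$abundance_meanlog, p$abundance_sdlog)
  n_de <- round(p$de_fraction * n)
  de_idx <- if (n_de > 0) sample(n, n_de) else integer(0)
  up <- rep(FALSE, n)
  if (n_de > 0) up[sample(de_idx, floor(n_de / 2))] <- TRUE
  mult <- rep(1, n)
  mult[de_idx] <- ifelse(up[de_idx], p$fold_change, 1 / p$fold_change)
  ab_ctrl <- abundance
  ab_trt <- abundance * mult
  direction <- rep("unchanged", n)
  direction[de_idx] <- ifelse(up[de_idx], "increased", "decreased")

  design <- tibble(
    sample_id = c(paste0("ctrl_", seq_len(p$n_replicates)),
                  paste0("trt_", seq_len(p$n_replicates))),
    condition = rep(p$conditions, each = p$n_replicates)
  )

  draw_counts <- function(lambda) {
    if (p$dispersion > 0) rnbinom(n, mu = lambda, size = 1 / p$dispersion)
    else rpois(n, lambda)
  }

  psm_chunks <- list()
  label_chunks <- list()
  for (si in seq_len(nrow(design))) {
    s <- design$sample_id[si]
    ab <- if (design$condition[si] == p$conditions[1]) ab_ctrl else ab_trt
    lambda <- p$depth * (ab * len) / sum(ab * len)
    cnt <- draw_counts(lambda)

    nz <- which(cnt > 0)
    prot_of_psm <- rep(nz, cnt[nz])
    pep_row <- unlist(lapply(nz, function(k) {
      rows <- cat_index[[as.character(k)]]
      rows[sample.int(length(rows), cnt[k], replace = TRUE)]
    }))
    n_correct <- length(prot_of_psm)

    n_inc <- rpois(1, p$incorrect_target_fraction * p$depth)
    inc_prot <- sample.int(n, n_inc, replace = TRUE)
    inc_pep_row <- vapply(inc_prot, function(k) {
      rows <- cat_index[[as.character(k)]]
      rows[sample.int(length(rows), 1)]
    }, integer(1))

    n_dec <- rpois(1, p$incorrect_target_fraction * p$depth)
    dec_prot <- sample.int(n, n_dec, replace = TRUE)
    dec_pep <- vapply(dec_prot, function(k) {
      rows <- cat_index[[as.character(k)]]
      pep <- pep_tbl$peptide[rows[sample.int(length(rows), 1)]]
      paste(rev(strsplit(pep, "", fixed = TRUE)[[1]]), collapse = "")
    }, character(1))

    target_rows <- c(seq_len(n_correct), n_correct + seq_len(n_inc))
    all_pep_row <- c(pep_row, inc_pep_row)
    target_proteins <- purrr::map(all_pep_row, function(r) {
      own <- accession[pep_tbl$owner[r]]
      if (is.na(pep_tbl$partner[r])) own
      else c(own, accession[pep_tbl$partner[r]])
    })

    n_tot <- n_correct + n_inc + n_dec
    chunk <- tibble(
      sample_id = s,
      spectrum_id = sprintf("%s_scan%06d", s, seq_len(n_tot)),
      peptide = c(pep_tbl$peptide[all_pep_row], dec_pep),
      proteins = c(target_proteins,
                   if (n_dec > 0) as.list(paste0(p$decoy_prefix, accession[dec_prot]))
                   else list()),
      score = c(rnorm(n_correct, p$target_score_mean, p$target_score_sd),
                rnorm(n_inc + n_dec, p$decoy_score_mean, p$decoy_score_sd)),
      is_decoy = c(rep(FALSE, n_correct + n_inc), rep(TRUE, n_dec))
    )
    psm_chunks[[si]] <- chunk
    label_chunks[[si]] <- tibble(
      sample_id = s, spectrum_id = chunk$spectrum_id,
      correct = c(rep(TRUE, n_correct), rep(FALSE, n_inc + n_dec))
    )
  }
  psms <- bind_rows(psm_chunks)
  psm_labels <- bind_rows(label_chunks)

  # GO annotations: term GO:0000001 enriched in the truly-DE set
  onts <- c("P", "C", "F")
  n_terms <- 30
  ann_chunks <- list()
  de_mask <- seq_len(n) %in% de_idx
  hit1 <- runif(n) < ifelse(de_mask, 0.6, 0.05)
  ann_chunks[[1]] <- tibble(
    accession = accession[hit1], term_id = "GO:0000001", ontology = "P",
    description = "synthetic heat response"
  )
  for (t in seq_len(n_terms)) {
    prob <- runif(1, 0.01, 0.1)
    hit <- runif(n) < prob
    ann_chunks[[t + 1]] <- tibble(
      accession = accession[hit],
      term_id = sprintf("GO:%07d", t + 1),
      ontology = onts[(t %% 3) + 1],
      description = sprintf("synthetic term %d", t + 1)
    )
  }
  annotations <- bind_rows(ann_chunks) %>%
    arrange(.data$term_id, .data$accession)

  truth <- list(
    proteins = tibble(
      accession = accession, length = len,
      abundance_control = ab_ctrl, abundance_treatment = ab_trt,
      is_de = de_mask, direction = direction
    ),
    psm_labels = psm_labels
  )

  out <- list(psms = psms, proteins = proteins, annotations = annotations,
              design = design, truth = truth, params = params)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_psm_table(psms, file.path(outdir, "psms.tsv"))
    write_fasta(proteins, file.path(outdir, "database.fasta"))
    readr::write_tsv(annotations, file.path(outdir, "go_annotations.tsv"))
    write_design(design, file.path(outdir, "design.yml"))
    readr::write_tsv(truth$proteins, file.path(outdir, "truth_proteins.tsv"))
    readr::write_tsv(truth$psm_labels, file.path(outdir, "truth_psms.tsv"))
  }
  out
}

#' Recovery of synthetic ground truth by the DE stage
#'
#' Compares differential-expression calls against the generator's truth:
#' sensitivity (flagged true positives over all true positives), realized
#' false discovery proportion (flagged non-DE over all flagged, 0 when
#' nothing is flagged), and direction accuracy over flagged true
#' positives.
#'
#' @param truth The `truth` element of [generate_experiment()] output.
#' @param de An `spc_de` tibble from [de_test()].
#' @param groups Optional grouping table; when given, DE row ids are
#'   mapped to their representative accession before matching.
#' @param min_mean_spc Restrict the true-positive set to proteins whose
#'   mean spectral count (over `counts`) is at least this value.
#' @param counts Count matrix, required when `min_mean_spc > 0`; row ids
#'   are mapped through `groups` the same way.
#' @param alpha Significance level for "flagged"; defaults to the
#'   [de_test()] alpha.
#' @return One-row tibble: `n_true`, `n_flagged`, `sensitivity`,
#'   `realized_fdr`, `direction_accuracy`.
#' @export
truth_recovery_report <- function(truth, de, groups = NULL,
                                  min_mean_spc = 0, counts = NULL,
                                  alpha = attr(de, "alpha") %||% 0.05) {
  map_id <- function(ids) {
    if (is.null(groups)) return(ids)
    groups$representative[match(ids, groups$group_id)]
  }
  de_acc <- map_id(de$id)
  flagged <- de_acc[de$p_value <= alpha]
  flagged_dir <- setNames(de$direction[de$p_value <= alpha], flagged)

  true_tbl <- truth$proteins %>% filter(.data$is_de)
  if (min_mean_spc > 0) {
    if (is.null(counts)) abort("`counts` is required when min_mean_spc > 0")
    cacc <- map_id(counts$id)
    mean_spc <- rowMeans(as.matrix(counts[, setdiff(names(counts), "id")]))
    ok <- cacc[mean_spc >= min_mean_spc]
    true_tbl <- true_tbl %>% filter(.data$accession %in% ok)
  }
  true_ids <- true_tbl$accession
  tp <- intersect(flagged, true_ids)
  dir_ok <- if (length(tp) > 0) {
    truth_dir <- setNames(true_tbl$direction, true_tbl$accession)
    mean(flagged_dir[tp] == truth_dir[tp])
  } else NA_real_
  tibble(
    n_true = length(true_ids),
    n_flagged = length(flagged),
    sensitivity = if (length(true_ids) > 0) length(tp) / length(true_ids) else NA_real_,
    realized_fdr = if (length(flagged) > 0) length(setdiff(flagged, true_ids)) / length(flagged) else 0,
    direction_accuracy = dir_ok
  )
}
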