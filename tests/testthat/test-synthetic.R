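small_params <- function(...) {
  synth_params(n_proteins = 150, depth = 2000, ...)
}

test_that("identical seeds give byte-identical generated files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_experiment(small_params(seed = 5), outdir = d1)
  generate_experiment(small_params(seed = 5), outdir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  # and a different seed changes the data
  e3 <- generate_experiment(small_params(seed = 6))
  e1 <- generate_experiment(small_params(seed = 5))
  expect_false(identical(e1$psms$score, e3$psms$score))
})

test_that("generated files re-read into the in-memory objects", {
  d <- withr::local_tempdir()
  exp <- generate_experiment(small_params(seed = 9), outdir = d)
  psms <- read_psm_table(file.path(d, "psms.tsv"))
  expect_equal(psms, exp$psms)
  db <- read_fasta(file.path(d, "database.fasta"))
  expect_equal(db$accession, exp$proteins$accession)
  expect_equal(db$sequence, exp$proteins$sequence)
  ann <- read_go_annotations(file.path(d, "go_annotations.tsv"))
  expect_equal(nrow(ann), nrow(exp$annotations))
  expect_equal(read_design(file.path(d, "design.yml")), exp$design)
})

test_that("per-sample correct-PSM totals track the requested depth", {
  p <- small_params(seed = 14)
  exp <- generate_experiment(p)
  totals <- table(exp$truth$psm_labels$sample_id[exp$truth$psm_labels$correct])
  expect_equal(length(totals), 6)
  expect_true(all(abs(as.numeric(totals) - p$depth) <= 3 * sqrt(p$depth)))
})

test_that("spiked proteins, truth labels and DE fraction are consistent", {
  p <- small_params(seed = 25, de_fraction = 0.2)
  exp <- generate_experiment(p)
  tr <- exp$truth$proteins
  expect_equal(sum(tr$is_de), round(0.2 * 150))
  expect_setequal(unique(tr$direction[tr$is_de]), c("increased", "decreased"))
  fc <- tr$abundance_treatment / tr$abundance_control
  expect_true(all(fc[tr$direction == "increased"] == p$fold_change))
  expect_true(all(fc[tr$direction == "decreased"] == 1 / p$fold_change))
  expect_true(all(fc[!tr$is_de] == 1))

  null_exp <- generate_experiment(small_params(seed = 26, de_fraction = 0))
  expect_equal(sum(null_exp$truth$proteins$is_de), 0)
})

test_that("without shared peptides the count matrix conserves PSMs exactly", {
  exp <- generate_experiment(small_params(seed = 33,
                                          shared_peptide_fraction = 0,
                                          incorrect_target_fraction = 0))
  scored <- compute_qvalues(exp$psms)
  kept <- filter_at_fdr(scored, 1)
  groups <- group_proteins(kept, exp$proteins)
  counts <- spectral_count_matrix(kept, groups, exp$design)
  mat <- as.matrix(counts[, exp$design$sample_id])
  expect_equal(sum(mat), nrow(kept))
})

test_that("decoy PSMs carry reversed accessions and low scores on average", {
  exp <- generate_experiment(small_params(seed = 41))
  dec <- exp$psms[exp$psms$is_decoy, ]
  expect_true(all(grepl("^rev_", unlist(dec$proteins))))
  tgt <- exp$psms[!exp$psms$is_decoy, ]
  expect_gt(mean(tgt$score), mean(dec$score))
})

test_that("spiked spectral-count ratios recover the programmed fold change", {
  p <- synth_params(n_proteins = 400, depth = 8000, seed = 1)
  ratios <- c()
  for (seed in 1:5) {
    p$seed <- seed
    exp <- generate_experiment(p)
    tr <- exp$truth$proteins
    lam_ctrl <- p$depth * tr$abundance_control * tr$length /
      sum(tr$abundance_control * tr$length)
    lam_trt <- p$depth * tr$abundance_treatment * tr$length /
      sum(tr$abundance_treatment * tr$length)
    ok <- exp$truth$psm_labels$correct
    psms <- exp$psms[ok, ]
    first_acc <- vapply(psms$proteins, `[[`, character(1), 1)
    m <- as.matrix(table(first_acc, psms$sample_id))
    ctl <- rowMeans(m[, grep("^ctrl", colnames(m)), drop = FALSE])
    trt <- rowMeans(m[, grep("^trt", colnames(m)), drop = FALSE])
    idx <- match(rownames(m), tr$accession)
    up <- tr$direction[idx] == "increased" & lam_ctrl[idx] >= 5
    dn <- tr$direction[idx] == "decreased" & lam_trt[idx] >= 5
    r <- c(trt[up] / ctl[up], ctl[dn] / trt[dn])
    ratios <- c(ratios, r[is.finite(r)])
  }
  expect_equal(mean(ratios), 8, tolerance = 0.3)
})

test_that("truth recovery report handles perfect and empty call sets", {
  truth <- list(proteins = tibble::tibble(
    accession = c("A", "B", "C", "D"),
    length = 100L,
    abundance_control = 1, abundance_treatment = c(8, 1/8, 1, 1),
    is_de = c(TRUE, TRUE, FALSE, FALSE),
    direction = c("increased", "decreased", "unchanged", "unchanged")
  ))
  de_perfect <- tibble::tibble(
    id = c("A", "B", "C", "D"),
    ratio = c(8, 1/8, 1, 1),
    p_value = c(0.001, 0.001, 0.9, 0.9),
    direction = c("increased", "decreased", "unchanged", "unchanged")
  )
  rec <- truth_recovery_report(truth, de_perfect, alpha = 0.05)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$realized_fdr, 0)
  expect_equal(rec$direction_accuracy, 1)

  de_none <- de_perfect
  de_none$p_value <- 1
  rec0 <- truth_recovery_report(truth, de_none, alpha = 0.05)
  expect_equal(rec0$sensitivity, 0)
  expect_equal(rec0$realized_fdr, 0)  # empty-call convention
})
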