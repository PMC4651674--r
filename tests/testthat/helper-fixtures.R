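# Small in-code fixtures shared across test files.

make_psms <- function(scores, is_decoy, proteins = NULL, sample_id = "s1",
                      peptide = "PEPTIDEK") {
  n <- length(scores)
  if (is.null(proteins)) proteins <- as.list(paste0("P", seq_len(n)))
  tibble::tibble(
    sample_id = rep_len(sample_id, n),
    spectrum_id = paste0("sp", seq_len(n)),
    peptide = rep_len(peptide, n),
    proteins = proteins,
    score = as.numeric(scores),
    is_decoy = is_decoy
  )
}

# PSMs in which each peptide maps to a fixed set of accessions; scores all
# pass any FDR cut
make_evidence <- function(pep2prot, sample_id = "s1") {
  tibble::tibble(
    sample_id = sample_id,
    spectrum_id = paste0("sp", seq_along(pep2prot)),
    peptide = names(pep2prot),
    proteins = unname(pep2prot),
    score = 100,
    is_decoy = FALSE
  )
}

make_design <- function(n_rep = 3, conditions = c("control", "treatment")) {
  tibble::tibble(
    sample_id = c(paste0("ctrl_", seq_len(n_rep)), paste0("trt_", seq_len(n_rep))),
    condition = rep(conditions, each = n_rep)
  )
}

write_tsv_lines <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".tsv",
                              .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}

# Direct term-by-term transcription of the NSpC definition, used as the
# independent oracle.
oracle_nspc <- function(spc, len, pseudocount = 0) {
  w <- numeric(length(spc))
  for (i in seq_along(spc)) w[i] <- (spc[i] + pseudocount) / len[i]
  out <- numeric(length(spc))
  for (k in seq_along(spc)) out[k] <- w[k] / sum(w)
  out
}

# independent vectorized Henderson-Hasselbalch net charge, used as the
# grid-scan oracle for the pI bisection
oracle_net_charge <- function(pH, seq, pkas = spcquant::emboss_pkas()) {
  res <- strsplit(seq, "")[[1]]
  cnt <- table(res)
  pos <- 1 / (1 + 10^(pH - pkas$nterm))
  neg <- 1 / (1 + 10^(pkas$cterm - pH))
  for (r in names(pkas$sidechain)) {
    n <- if (r %in% names(cnt)) cnt[[r]] else 0
    if (n == 0) next
    if (pkas$sign[[r]] == "basic") {
      pos <- pos + n / (1 + 10^(pH - pkas$sidechain[[r]]))
    } else {
      neg <- neg + n / (1 + 10^(pkas$sidechain[[r]] - pH))
    }
  }
  pos - neg
}

random_aa_seq <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}
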