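#' Read a PSM table
#'
#' Reads a tab-separated table of peptide-spectrum matches (PSMs), the
#' search-engine output consumed by the rest of the pipeline. The dialect is
#' UTF-8, tab-separated, with a header row and `#` comment lines ignored.
#' Required columns are `sample_id`, `spectrum_id`, `peptide`, `proteins`
#' (candidate parent accessions, semicolon-separated, order preserved) and
#' `score` (higher is better). An optional logical `is_decoy` column
#' overrides prefix-based decoy detection; without it a PSM is a decoy iff
#' every candidate accession starts with `decoy_prefix`.
#'
#' @param path Path to the PSM TSV file.
#' @param decoy_prefix Accession prefix marking reversed-sequence decoys.
#' @return A tibble with one row per PSM: `sample_id`, `spectrum_id`,
#'   `peptide`, `proteins` (list-column of character vectors), `score`
#'   (double) and `is_decoy` (logical).
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tspectrum_id\tpeptide\tproteins\tscore",
#'              "s1\tsp1\tPEPTIDE\tA;B\t31.5"), tf)
#' read_psm_table(tf)
#' @export
read_psm_table <- function(path, decoy_prefix = "rev_") {
  stopifnot(is.character(path), length(path) == 1)
  if (!file.exists(path)) {
    abort(paste0("PSM table not found: ", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(trimws(lines), "#") & nzchar(lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    abort(paste0("PSM table has no header row: ", path))
  }
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  required <- c("sample_id", "spectrum_id", "peptide", "proteins", "score")
  missing <- setdiff(required, header)
  if (length(missing) > 0) {
    abort(paste0("PSM table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  body <- lines[-1]
  if (length(body) == 0) {
    warn(paste0("PSM table contains a header but no data rows: ", path))
    return(empty_psm_table())
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  idx <- setNames(seq_along(header), header)
  col <- function(nm) vapply(fields, function(f) f[[idx[[nm]]]], character(1))

  score_chr <- col("score")
  score <- suppressWarnings(as.numeric(score_chr))
  if (anyNA(score)) {
    bad <- which(is.na(score))[1]
    abort(sprintf("non-numeric score %s at line %d of %s",
                  dQuote(score_chr[bad]), line_no[-1][bad], path))
  }

  peptide <- toupper(col("peptide"))
  bad_pep <- !grepl(paste0("^[", paste(STANDARD_AA, collapse = ""), "]+$"), peptide)
  if (any(bad_pep)) {
    bad <- which(bad_pep)[1]
    abort(sprintf("peptide %s at line %d is empty or outside the 20 standard residues",
                  dQuote(peptide[bad]), line_no[-1][bad]))
  }

  proteins <- strsplit(col("proteins"), ";", fixed = TRUE)
  if (any(lengths(proteins) == 0 | vapply(proteins, function(p) any(!nzchar(p)), logical(1)))) {
    bad <- which(lengths(proteins) == 0)[1]
    abort(sprintf("empty protein accession list at line %d", line_no[-1][bad]))
  }

  if ("is_decoy" %in% header) {
    is_decoy <- toupper(col("is_decoy")) %in% c("TRUE", "T", "1", "YES")
  } else {
    is_decoy <- vapply(proteins, function(p) all(startsWith(p, decoy_prefix)),
                       logical(1))
  }

  tibble(
    sample_id = col("sample_id"),
    spectrum_id = col("spectrum_id"),
    peptide = peptide,
    proteins = proteins,
    score = score,
    is_decoy = is_decoy
  )
}

empty_psm_table <- function() {
  tibble(
    sample_id = character(), spectrum_id = character(),
    peptide = character(), proteins = list(),
    score = double(), is_decoy = logical()
  )
}

#' Write a PSM table
#'
#' Inverse of [read_psm_table()]: writing and re-reading a table yields
#' identical records.
#'
#' @param psms A PSM tibble as returned by [read_psm_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  out <- psms %>%
    mutate(proteins = vapply(.data$proteins, paste, character(1), collapse = ";"),
           is_decoy = ifelse(.data$is_decoy, "TRUE", "FALSE"))
  readr::write_tsv(out, path, escape = "none")
  invisible(path)
}

#' Read a protein database from FASTA
#'
#' The accession is the first whitespace-delimited token of each header; the
#' remainder of the header, if any, is kept as the description. Sequences
#' must use the extended IUPAC amino-acid alphabet and accessions must be
#' unique within the database.
#'
#' @param path Path to a FASTA file of protein sequences.
#' @return A tibble with columns `accession`, `description`, `sequence` and
#'   `length` (number of residues).
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readBStringSet(path)
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0) {
    abort(paste0("duplicate accession(s) in FASTA: ",
                 paste(unique(dup), collapse = ", ")))
  }
  sequence <- toupper(as.character(aa))
  ok <- grepl(paste0("^[", paste(EXTENDED_AA, collapse = ""), "]*$"), sequence)
  if (any(!ok)) {
    abort(paste0("sequence with non-IUPAC amino-acid characters in record(s): ",
                 paste(accession[!ok], collapse = ", ")))
  }
  tibble(
    accession = unname(accession),
    description = unname(description),
    sequence = unname(sequence),
    length = nchar(sequence)
  )
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Tibble with `accession`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- proteins$accession
  if ("description" %in% names(proteins)) {
    hdr <- ifelse(nzchar(proteins$description),
                  paste(hdr, proteins$description), hdr)
  }
  seqs <- Biostrings::BStringSet(setNames(proteins$sequence, hdr))
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Read a GO annotation table
#'
#' A four-column TSV (`accession`, `term_id`, `ontology`, `description`)
#' mapping proteins to GO terms. Annotations are assumed to be already
#' propagated to ancestor terms by the provider; no DAG traversal is done
#' downstream. Term ids must match `GO:` followed by exactly seven digits
#' and the ontology code must be one of `P` (biological process), `C`
#' (cellular component) or `F` (molecular function). Duplicate
#' accession/term pairs are collapsed to one row.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble with columns `accession`, `term_id`, `ontology`,
#'   `description`.
#' @export
read_go_annotations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        comment = "#", progress = FALSE)
  required <- c("accession", "term_id", "ontology", "description")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(paste0("GO annotation table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  bad_term <- !grepl("^GO:[0-9]{7}$", df$term_id)
  if (any(bad_term)) {
    abort(paste0("malformed GO term id(s) at data row(s) ",
                 paste(which(bad_term), collapse = ", "),
                 " (expected GO: followed by 7 digits)"))
  }
  bad_ont <- !df$ontology %in% c("P", "C", "F")
  if (any(bad_ont)) {
    abort(paste0("ontology code outside {P, C, F} at data row(s) ",
                 paste(which(bad_ont), collapse = ", ")))
  }
  df %>%
    select(all_of(required)) %>%
    distinct(.data$accession, .data$term_id, .keep_all = TRUE)
}

#' Read an experiment design
#'
#' The design is a YAML file mapping condition names to the ordered list of
#' sample ids belonging to them, e.g.
#' ```
#' conditions:
#'   control: [ctrl_1, ctrl_2, ctrl_3]
#'   treatment: [trt_1, trt_2, trt_3]
#' ```
#' Every condition needs at least two biological replicates and sample ids
#' must be globally unique.
#'
#' @param path Path to the YAML design file.
#' @return A tibble with columns `sample_id` and `condition`, ordered as in
#'   the file.
#' @export
read_design <- function(path) {
  cfg <- yaml::read_yaml(path)
  conditions <- cfg$conditions %||% cfg
  design <- purrr::imap(conditions, function(samples, cond) {
    tibble(sample_id = as.character(unlist(samples)), condition = cond)
  }) %>% bind_rows()
  validate_design(design)
  design
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design),
            all(c("sample_id", "condition") %in% names(design)))
  if (anyDuplicated(design$sample_id)) {
    abort("sample ids in the design must be globally unique")
  }
  reps <- table(design$condition)
  if (any(reps < 2)) {
    abort(paste0("every condition needs >= 2 replicates; offending: ",
                 paste(names(reps)[reps < 2], collapse = ", ")))
  }
  invisible(design)
}

#' Write an experiment design to YAML
#'
#' @param design Tibble with `sample_id` and `condition` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  conditions <- split(design$sample_id, design$condition)
  # preserve condition order of first appearance
  conditions <- conditions[unique(design$condition)]
  yaml::write_yaml(list(conditions = lapply(conditions, as.list)), path)
  invisible(path)
}
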