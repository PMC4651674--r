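#' Group proteins by shared peptide evidence
#'
#' Protein accessions that cannot be distinguished by the observed peptides
#' are collapsed into groups: accessions with identical observed peptide
#' sets merge, and an accession whose peptide set is a strict subset of
#' another accession's set is subsumed into that accession's group. Only
#' observed peptides count — no theoretical digest is consulted. The
#' result satisfies the maximality property that no group's peptide set is
#' a strict subset of another group's.
#'
#' The representative of a group is the member with the most distinct
#' observed peptides; ties are broken by greater sequence length (when
#' `proteins` is supplied), then by lexicographic accession. When an
#' accession's set is a strict subset of several incomparable supersets it
#' is assigned to the group with the largest peptide set, ties broken by
#' representative accession.
#'
#' @param psms FDR-filtered target PSM tibble.
#' @param proteins Optional protein database tibble from [read_fasta()];
#'   required when group lengths (`L` of the NSpC normalization) are
#'   wanted. Every observed accession must then be present.
#' @return A tibble with one row per group: `group_id`, `representative`,
#'   `members` (list-column), `n_members`, `peptides` (list-column of the
#'   group's peptide set), `n_peptides` and `length` (representative's
#'   sequence length, `NA` without `proteins`).
#' @export
group_proteins <- function(psms, proteins = NULL) {
  stopifnot(is.data.frame(psms), all(c("peptide", "proteins") %in% names(psms)))
  if (nrow(psms) == 0) {
    return(tibble(group_id = character(), representative = character(),
                  members = list(), n_members = integer(),
                  peptides = list(), n_peptides = integer(),
                  length = integer()))
  }
  pairs <- tibble(
    peptide = rep(psms$peptide, lengths(psms$proteins)),
    accession = unlist(psms$proteins)
  ) %>% distinct()

  pepsets <- split(pairs$peptide, pairs$accession)
  pepsets <- lapply(pepsets, function(p) sort(unique(p)))
  accs <- names(pepsets)

  lengths_by_acc <- NULL
  if (!is.null(proteins)) {
    missing <- setdiff(accs, proteins$accession)
    if (length(missing) > 0) {
      abort(paste0("accession(s) absent from the protein database: ",
                   paste(missing, collapse = ", ")))
    }
    lengths_by_acc <- setNames(proteins$length, proteins$accession)
  }

  # identical-set merge: one cluster per distinct peptide set
  key <- vapply(pepsets, paste, character(1), collapse = "\r")
  clusters <- split(accs, key)
  cl_peps <- lapply(clusters, function(a) pepsets[[a[[1]]]])
  nset <- length(clusters)

  # subsumption: strict-subset clusters fold into a maximal superset.
  # A peptide -> cluster index prunes the search: a superset of cluster i
  # must contain every one of i's peptides, so candidates are the
  # intersection of the index entries over i's peptides.
  sizes <- lengths(cl_peps)
  pep2cl <- split(rep(seq_len(nset), sizes), unlist(cl_peps))
  parent <- seq_len(nset)
  for (i in seq_len(nset)) {
    peps <- cl_peps[[i]]
    cands <- pep2cl[[peps[1]]]
    for (pp in peps[-1]) {
      if (length(cands) <= 1) break
      cands <- intersect(cands, pep2cl[[pp]])
    }
    supersets <- cands[sizes[cands] > sizes[i]]
    if (length(supersets) > 0) {
      # largest superset wins; ties by representative accession
      best <- supersets[order(-sizes[supersets],
                              vapply(supersets, function(j)
                                pick_representative(clusters[[j]], pepsets,
                                                    lengths_by_acc),
                                character(1)))][1]
      parent[i] <- best
    }
  }
  # path-compress (a subset's superset may itself be subsumed)
  for (i in seq_len(nset)) {
    while (parent[parent[i]] != parent[i]) parent[i] <- parent[parent[i]]
  }

  groups <- split(seq_len(nset), parent)
  members <- lapply(groups, function(idx) sort(unique(unlist(clusters[idx]))))
  peps <- lapply(groups, function(idx) {
    # the maximal cluster's set already contains all subsumed sets
    cl_peps[[idx[which.max(sizes[idx])]]]
  })
  rep_acc <- vapply(members, pick_representative, character(1),
                    pepsets = pepsets, lengths_by_acc = lengths_by_acc)
  out <- tibble(
    representative = unname(rep_acc),
    members = unname(members),
    n_members = unname(lengths(members)),
    peptides = unname(peps),
    n_peptides = unname(lengths(peps)),
    length = if (is.null(lengths_by_acc)) NA_integer_
             else as.integer(lengths_by_acc[rep_acc])
  ) %>%
    arrange(.data$representative) %>%
    mutate(group_id = paste0("grp_", .data$representative), .before = 1)
  out
}

# most distinct peptides, then longer sequence, then lexicographic accession
pick_representative <- function(members, pepsets, lengths_by_acc) {
  npep <- vapply(members, function(a) length(pepsets[[a]]), integer(1))
  len <- if (is.null(lengths_by_acc)) rep(0L, length(members))
         else as.integer(lengths_by_acc[members])
  members[order(-npep, -len, members)][1]
}

#' Spectral count matrix per group and sample
#'
#' Counts peptide-spectrum matches per protein group and sample. A PSM
#' increments the count of every group containing any of its candidate
#' accessions, so spectra from shared peptides are counted redundantly in
#' each matching group; counts are spectrum counts, not distinct-peptide
#' counts.
#'
#' @param psms FDR-filtered target PSM tibble.
#' @param groups Output of [group_proteins()].
#' @param design Design tibble (`sample_id`, `condition`); every PSM's
#'   sample must appear in it. All design samples appear as columns, with
#'   zero counts where a sample yielded no PSM.
#' @return A tibble with `id` (group id) and one integer column per
#'   sample.
#' @export
spectral_count_matrix <- function(psms, groups, design) {
  validate_design(design)
  bad <- setdiff(unique(psms$sample_id), design$sample_id)
  if (length(bad) > 0) {
    abort(paste0("PSM sample id(s) not in the design: ",
                 paste(bad, collapse = ", ")))
  }
  acc2group <- tibble(
    group_id = rep(groups$group_id, lengths(groups$members)),
    accession = unlist(groups$members)
  )
  hits <- tibble(
    psm = rep(seq_len(nrow(psms)), lengths(psms$proteins)),
    accession = unlist(psms$proteins),
    sample_id = rep(psms$sample_id, lengths(psms$proteins))
  ) %>%
    dplyr::inner_join(acc2group, by = "accession",
                      relationship = "many-to-many") %>%
    distinct(.data$psm, .data$sample_id, .data$group_id)
  unmapped <- setdiff(seq_len(nrow(psms)), unique(hits$psm))
  if (length(unmapped) > 0) {
    abort(paste0(length(unmapped),
                 " PSM(s) map to no group; regroup from the same PSM set"))
  }
  counts <- hits %>%
    count(.data$group_id, .data$sample_id) %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "n",
                       values_fill = 0L)
  for (s in setdiff(design$sample_id, names(counts))) {
    counts[[s]] <- 0L
  }
  counts %>%
    rename(id = "group_id") %>%
    select("id", all_of(design$sample_id)) %>%
    arrange(.data$id)
}
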