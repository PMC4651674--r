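# Average and monoisotopic residue masses (Da) for the 20 standard amino
# acids, plus the mass of one water added per chain.
AVG_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
MONO_RESIDUE_MASS <- c(
  A = 71.03711,  R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146,  H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203,  T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)
WATER_AVG <- 18.01524
WATER_MONO <- 18.010565

#' Protein molecular weight
#'
#' Sum of residue masses plus one water, with no modification masses.
#' Average masses by default (what EMBOSS Pepstats reports); monoisotopic
#' masses on request.
#'
#' @param sequence One or more amino-acid strings (20 standard residues).
#' @param monoisotopic Use monoisotopic instead of average masses.
#' @return Numeric vector of masses in daltons.
#' @examples
#' molecular_weight("G")   # 75.07 Da
#' @export
molecular_weight <- function(sequence, monoisotopic = FALSE) {
  masses <- if (monoisotopic) MONO_RESIDUE_MASS else AVG_RESIDUE_MASS
  water <- if (monoisotopic) WATER_MONO else WATER_AVG
  vapply(sequence, function(s) {
    if (!nzchar(s)) abort("molecular weight of an empty sequence is undefined")
    res <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    unknown <- which(!res %in% names(masses))
    if (length(unknown) > 0) {
      abort(sprintf("unknown residue %s at position %d",
                    dQuote(res[unknown[1]]), unknown[1]))
    }
    sum(masses[res]) + water
  }, numeric(1), USE.NAMES = FALSE)
}

#' The EMBOSS Pepstats pKa set
#'
#' Ionizable-group pKa values as shipped with EMBOSS Pepstats (Edata file
#' `Epk.dat`): amino terminus 8.6, carboxyl terminus 3.6, and side chains
#' C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1. Acidic groups (C,
#' D, E, Y and the C-terminus) contribute negative charge above their pKa;
#' basic groups (H, K, R and the N-terminus) contribute positive charge
#' below theirs. Cysteine is treated as ionizable, as plain Pepstats does,
#' even in experiments that alkylate cysteines.
#'
#' @return A list with components `nterm`, `cterm` (scalars) and
#'   `sidechain` (named vector over C, D, E, H, K, R, Y), plus `sign`
#'   marking each side chain acidic or basic.
#' @export
emboss_pkas <- function() {
  list(
    name = "EMBOSS Pepstats defaults",
    nterm = 8.6,
    cterm = 3.6,
    sidechain = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5,
                  K = 10.8, R = 12.5, Y = 10.1),
    sign = c(C = "acidic", D = "acidic", E = "acidic", H = "basic",
             K = "basic", R = "basic", Y = "acidic")
  )
}

net_charge_at <- function(pH, comp, pkas) {
  # basic groups: +1 when protonated; acidic: -1 when deprotonated
  pos <- 1 / (1 + 10^(pH - pkas$nterm))
  neg <- 1 / (1 + 10^(pkas$cterm - pH))
  for (res in names(pkas$sidechain)) {
    n <- comp[[res]] %||% 0
    if (n == 0) next
    pk <- pkas$sidechain[[res]]
    if (pkas$sign[[res]] == "basic") {
      pos <- pos + n / (1 + 10^(pH - pk))
    } else {
      neg <- neg + n / (1 + 10^(pk - pH))
    }
  }
  pos - neg
}

#' Protein isoelectric point
#'
#' The pH at which the net charge of the chain is zero under the
#' Henderson-Hasselbalch model, summing over the two termini and the
#' ionizable side chains. Net charge is strictly decreasing in pH (every
#' group only loses positive or gains negative charge as pH rises), so
#' the root is unique; it is located by bisection on [0, 14] to a pH
#' tolerance of 1e-4. The function depends only on residue composition,
#' not on residue order.
#'
#' @param sequence One or more amino-acid strings.
#' @param pkas A pKa set as returned by [emboss_pkas()] (the default).
#' @param tol Bisection tolerance in pH units.
#' @return Numeric vector of isoelectric points (pH units).
#' @examples
#' isoelectric_point("AAA")  # (8.6 + 3.6) / 2 = 6.1
#' isoelectric_point("K")    # (8.6 + 10.8) / 2 = 9.7
#' @export
isoelectric_point <- function(sequence, pkas = emboss_pkas(), tol = 1e-4) {
  vapply(sequence, function(s) {
    if (!nzchar(s)) abort("isoelectric point of an empty sequence is undefined")
    res <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    bad <- which(!res %in% STANDARD_AA)
    if (length(bad) > 0) {
      abort(sprintf("unknown residue %s at position %d", dQuote(res[bad[1]]), bad[1]))
    }
    comp <- as.list(table(res))
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (net_charge_at(mid, comp, pkas) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1), USE.NAMES = FALSE)
}

#' Physico-chemical profile of a protein set
#'
#' Computes molecular weight and isoelectric point for every protein in a
#' database and flags which ones belong to an identified set, the input
#' for comparing the identified subproteome's pI/MW distributions against
#' the whole proteome.
#'
#' @param proteins Protein tibble from [read_fasta()].
#' @param identified Character vector of identified accessions (subset of
#'   the database).
#' @param pkas pKa set for the pI computation.
#' @return The protein tibble with added columns `mw_da`, `pi` and
#'   `identified` (logical).
#' @export
physchem_profile <- function(proteins, identified = character(),
                             pkas = emboss_pkas()) {
  missing <- setdiff(identified, proteins$accession)
  if (length(missing) > 0) {
    abort(paste0("identified accession(s) absent from the database: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  # X and other ambiguity codes carry no defined mass/pKa; map to NA
  clean <- grepl(paste0("^[", paste(STANDARD_AA, collapse = ""), "]+$"),
                 proteins$sequence)
  mw <- rep(NA_real_, nrow(proteins))
  pi <- rep(NA_real_, nrow(proteins))
  mw[clean] <- molecular_weight(proteins$sequence[clean])
  pi[clean] <- isoelectric_point(proteins$sequence[clean], pkas = pkas)
  proteins %>%
    mutate(mw_da = mw, pi = pi,
           identified = .data$accession %in% identified)
}

#' Binned distributions of a property in two populations
#'
#' Tallies per-bin fractions of a numeric property (pI, molecular weight,
#' ...) for a set of values and a reference population, e.g. identified
#' proteins versus the whole proteome. Values falling outside the
#' outermost edges are clamped into the end bins with a warning. Each
#' population's fractions sum to 1.
#'
#' @param values Named numeric vector (accession -> value) for the focal
#'   population.
#' @param reference Named numeric vector for the reference population.
#' @param bin_edges Strictly increasing numeric vector of bin boundaries;
#'   bins are left-closed, right-open except the last (right-closed).
#' @param labels Population labels, `c(focal, reference)`.
#' @return A tibble `bin` (factor, ordered), `bin_lo`, `bin_hi`,
#'   `population`, `n`, `fraction`.
#' @export
profile_distributions <- function(values, reference, bin_edges,
                                  labels = c("identified", "reference")) {
  stopifnot(length(bin_edges) >= 2, all(diff(bin_edges) > 0))
  tally <- function(v, pop) {
    out_of_range <- sum(v < bin_edges[1] | v > bin_edges[length(bin_edges)])
    if (out_of_range > 0) {
      warn(sprintf("%d %s value(s) outside the bin range; clamped into end bins",
                   out_of_range, pop))
      v <- pmin(pmax(v, bin_edges[1]), bin_edges[length(bin_edges)])
    }
    idx <- findInterval(v, bin_edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    n <- tabulate(idx, nbins = length(bin_edges) - 1)
    tibble(
      bin_lo = bin_edges[-length(bin_edges)],
      bin_hi = bin_edges[-1],
      population = pop, n = n, fraction = n / sum(n)
    )
  }
  out <- bind_rows(tally(values, labels[1]), tally(reference, labels[2]))
  out$bin <- factor(sprintf("[%g, %g)", out$bin_lo, out$bin_hi),
                    levels = unique(sprintf("[%g, %g)", out$bin_lo, out$bin_hi)))
  select(out, "bin", "bin_lo", "bin_hi", "population", "n", "fraction")
}
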