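# Monoisotopic residue masses (Da), standard 20 amino acids.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)
MASS_WATER <- 18.0105646863
MASS_PROTON <- 1.00727646688
MOD_CARBAMIDOMETHYL <- 57.02146
MOD_MET_OX <- 15.99491
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus water, with
#' carbamidomethyl-cysteine as an optional fixed modification and a given
#' number of oxidized methionines.
#'
#' @param sequence amino-acid string (20-letter alphabet).
#' @param carbamidomethyl apply +57.02146 per cysteine (default TRUE).
#' @param n_mox number of oxidized methionines (+15.99491 each).
#' @return Mass in Da.
#' @export
peptide_mass <- function(sequence, carbamidomethyl = TRUE, n_mox = 0) {
  aa <- strsplit(sequence, "")[[1]]
  if (any(!aa %in% names(AA_MONO)))
    stopf("invalid residue(s): %s",
          paste(unique(aa[!aa %in% names(AA_MONO)]), collapse = ", "))
  if (n_mox > sum(aa == "M")) stopf("n_mox exceeds methionine count")
  sum(AA_MONO[aa]) + MASS_WATER +
    (if (carbamidomethyl) sum(aa == "C") * MOD_CARBAMIDOMETHYL else 0) +
    n_mox * MOD_MET_OX
}

#' @noRd
mz_of <- function(mass, z) (mass + z * MASS_PROTON) / z

# 0-based cleavage points after K/R not followed by P.
#' @noRd
cleavage_sites <- function(aa) {
  n <- length(aa)
  which(aa %in% c("K", "R") & seq_along(aa) < n &
          c(aa[-1], "")[seq_along(aa)] != "P")
}

#' In-silico tryptic digest
#'
#' Cleaves C-terminal to K or R, suppressed when the next residue is P
#' (the classical trypsin rule), and emits every peptide with up to
#' `max_missed` missed cleavages, ordered by start position then missed
#' count.
#'
#' @param protein amino-acid string.
#' @param max_missed maximum missed cleavages (default 2).
#' @param carbamidomethyl fixed Cys carbamidomethylation for the mass
#'   column.
#' @return data.frame: `sequence`, `start` (1-based), `end`, `missed`,
#'   `mono_mass`, `mz_2` .. `mz_5`.
#' @export
tryptic_digest <- function(protein, max_missed = 2, carbamidomethyl = TRUE) {
  aa <- strsplit(protein, "")[[1]]
  if (any(!aa %in% names(AA_MONO)))
    stopf("invalid residue(s): %s",
          paste(unique(aa[!aa %in% names(AA_MONO)]), collapse = ", "))
  cuts <- cleavage_sites(aa)
  bounds <- c(0L, cuts, length(aa))          # fragment boundaries
  nfrag <- length(bounds) - 1L
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  for (i in seq_len(nfrag)) for (m in 0:max_missed) {
    if (i + m > nfrag) next
    starts <- c(starts, bounds[i] + 1L)
    ends <- c(ends, bounds[i + m + 1L])
    missed <- c(missed, m)
  }
  seqs <- substring(protein, starts, ends)
  # additive mass via cumulative sums (fast for many peptides)
  res_mass <- AA_MONO[aa] +
    (if (carbamidomethyl) (aa == "C") * MOD_CARBAMIDOMETHYL else 0)
  cum <- c(0, cumsum(res_mass))
  mass <- cum[ends + 1L] - cum[starts] + MASS_WATER
  out <- data.frame(sequence = seqs, start = starts, end = ends,
                    missed = missed, mono_mass = mass,
                    mz_2 = mz_of(mass, 2), mz_3 = mz_of(mass, 3),
                    mz_4 = mz_of(mass, 4), mz_5 = mz_of(mass, 5),
                    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$missed), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variant tryptic-peptide inclusion list
#'
#' For each of the 20 amino-acid substitutions at one site, finds the
#' minimal-missed-cleavage tryptic peptide spanning the site with at
#' least one residue of context on each side (so the variant is
#' positionally unambiguous; K/R substitutions create a new cleavage
#' point at the site, forcing their spanning peptide to carry a missed
#' cleavage) — the targeted-MS inclusion list used to quantify which
#' amino acid a suppressor tRNA inserts at the reporter's PTC position.
#'
#' @param protein amino-acid string (the reporter, e.g. an sfGFP-tag
#'   construct).
#' @param site 1-based substitution position.
#' @param max_missed maximum missed cleavages considered.
#' @param carbamidomethyl fixed Cys carbamidomethylation.
#' @return data.frame of exactly 20 rows (one per `variant_aa`, all
#'   sequences distinct): `variant_aa`, `sequence`, `start`, `end`,
#'   `missed`, `n_met`, `mono_mass`, `mz_2` .. `mz_5`. A protein with no
#'   cleavage sites yields the whole protein with a warning.
#' @export
variant_inclusion_list <- function(protein, site, max_missed = 2,
                                   carbamidomethyl = TRUE) {
  if (site < 1 || site > nchar(protein)) stopf("site out of protein range")
  lo <- max(1L, site - 1L)
  hi <- min(nchar(protein), site + 1L)
  rows <- lapply(AA20, function(v) {
    p <- protein
    substr(p, site, site) <- v
    dig <- tryptic_digest(p, max_missed, carbamidomethyl)
    span <- dig[dig$start <= lo & dig$end >= hi, , drop = FALSE]
    if (!nrow(span)) {
      warnf("no tryptic peptide spans site %d for variant %s; using whole protein",
            site, v)
      mass <- peptide_mass(p, carbamidomethyl)
      span <- data.frame(sequence = p, start = 1L, end = nchar(p),
                         missed = 0L, mono_mass = mass,
                         mz_2 = mz_of(mass, 2), mz_3 = mz_of(mass, 3),
                         mz_4 = mz_of(mass, 4), mz_5 = mz_of(mass, 5),
                         stringsAsFactors = FALSE)
    }
    span <- span[order(span$missed, span$end - span$start), , drop = FALSE]
    cbind(variant_aa = v, span[1, , drop = FALSE],
          n_met = lengths(regmatches(span$sequence[1],
                                     gregexpr("M", span$sequence[1]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$sequence))
    warnf("inclusion list has non-distinct peptide sequences")
  out
}

#' Expanded m/z table for an inclusion list
#'
#' One row per (peptide, charge 2..5, methionine-oxidation count): the
#' flat list handed to the instrument. Oxidized-methionine variable
#' modifications expand each peptide by its methionine count.
#'
#' @param inclusion a [variant_inclusion_list] result.
#' @return data.frame: `variant_aa`, `sequence`, `z`, `n_mox`, `mz`,
#'   `mods`.
#' @export
inclusion_mz_table <- function(inclusion) {
  rows <- list()
  for (r in seq_len(nrow(inclusion))) {
    n_m <- inclusion$n_met[r]
    for (n_mox in 0:n_m) {
      mass <- peptide_mass(inclusion$sequence[r], n_mox = n_mox)
      for (z in 2:5) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant_aa = inclusion$variant_aa[r],
          sequence = inclusion$sequence[r], z = z, n_mox = n_mox,
          mz = mz_of(mass, z),
          mods = if (n_mox > 0) sprintf("%dxOxidation(M)", n_mox) else "",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Ionization weights from an equimolar control
#'
#' Peptides ionize with different efficiencies, so raw abundances from an
#' equimolar mix of all variants are not uniform. The correction weight
#' for each amino acid is `mean(control) / control_aa`: reweighting the
#' control itself makes it exactly uniform. Amino acids with zero or
#' missing control abundance are excluded with a warning.
#'
#' @param control named numeric vector of per-amino-acid abundances from
#'   the equimolar control sample.
#' @return Named numeric weights (same names, excluded aa dropped).
#' @export
ionization_weights <- function(control) {
  if (is.null(names(control))) stopf("control must be named by amino acid")
  bad <- !is.finite(control) | control <= 0
  if (any(bad)) {
    warnf("excluding amino acid(s) with no control abundance: %s",
          paste(names(control)[bad], collapse = ", "))
    control <- control[!bad]
  }
  if (!length(control)) stopf("no usable control abundances")
  mean(control) / control
}

#' Ionization-weighted percent incorporation
#'
#' Applies control-derived ionization weights to a sample's per-amino-acid
#' abundances and normalizes to percentages:
#' `percent_aa = 100 * sample_aa * weight_aa / sum(sample * weight)`.
#' Amino acids absent from the weights are dropped (they were
#' undetectable in the control).
#'
#' @param sample named numeric vector of per-amino-acid abundances.
#' @param weights result of [ionization_weights].
#' @return data.frame of class `"incorporation_table"`: `aa`,
#'   `raw_abundance`, `ionization_weight`, `weighted_abundance`,
#'   `percent` (summing to 100), sorted by decreasing percent.
#' @export
percent_incorporation <- function(sample, weights) {
  if (is.null(names(sample))) stopf("sample must be named by amino acid")
  keep <- names(sample)[names(sample) %in% names(weights)]
  if (!length(keep)) stopf("no sample amino acid has a weight")
  s <- sample[keep]
  if (all(s <= 0)) stopf("all sample abundances are zero")
  w <- weights[keep]
  wa <- s * w
  out <- data.frame(aa = keep, raw_abundance = unname(s),
                    ionization_weight = unname(w),
                    weighted_abundance = unname(wa),
                    percent = unname(100 * wa / sum(wa)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$percent), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("incorporation_table", class(out))
  out
}

#' @export
print.incorporation_table <- function(x, ...) {
  cat("<incorporation_table> percent incorporation by amino acid\n")
  print.data.frame(data.frame(aa = x$aa,
                              percent = sprintf("%.3f", x$percent)))
  invisible(x)
}
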