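#' Activity-weighted sequence set
#'
#' Fixed-length sequences with nonnegative integer copy counts. The screen
#' trick behind the logos: a member's normalized suppression ratio is
#' treated as its sequence abundance (a ratio of 100 counts as 100 copies),
#' so activity weighting reduces to plain counting on the expanded set.
#'
#' @param sequences character vector of equal-length DNA strings.
#' @param counts nonnegative integer copies per sequence.
#' @return Object of class `"weighted_seq_set"`.
#' @export
weighted_seq_set <- function(sequences, counts) {
  if (length(sequences) != length(counts))
    stopf("sequences and counts differ in length")
  if (length(unique(nchar(sequences))) > 1)
    stopf("sequences must all have the same length")
  counts <- as.integer(round(counts))
  if (any(counts < 0)) stopf("counts must be >= 0")
  if (sum(counts) < 1) stopf("total weight must be >= 1")
  structure(list(sequences = sequences, counts = counts,
                 width = nchar(sequences[1])),
            class = "weighted_seq_set")
}

#' @export
print.weighted_seq_set <- function(x, ...) {
  cat(sprintf("<weighted_seq_set> %d sequence(s) x %d nt, total weight %d\n",
              length(x$sequences), x$width, sum(x$counts)))
  invisible(x)
}

#' Convert screen results to activity-derived copy counts
#'
#' Rounds each member's mean suppression ratio to an integer copy count
#' (R's default round-half-to-even; negative means floor at 0). Members
#' rounding to 0 are retained with count 0 and simply contribute nothing
#' to the totals.
#'
#' @param results a [summarize_library] result (or any data.frame with
#'   `member_id` and `mean`).
#' @param sequences named character vector or data.frame
#'   (`member_id`, `seq`) mapping members to their equal-length element
#'   sequences.
#' @return A [weighted_seq_set].
#' @export
weight_to_counts <- function(results, sequences) {
  if (is.data.frame(sequences)) {
    seqs <- sequences$seq
    names(seqs) <- sequences$member_id
    sequences <- seqs
  }
  j <- match(results$member_id, names(sequences))
  if (anyNA(j))
    stopf("no sequence for member(s): %s",
          paste(results$member_id[is.na(j)], collapse = ", "))
  weighted_seq_set(unname(sequences[j]), pmax(0, round(results$mean)))
}

#' Position frequency matrix of a weighted sequence set
#'
#' `freq[p, b]` = total weight of sequences carrying base b at position p,
#' divided by the total weight. Identical to plain counting on the
#' count-expanded set.
#'
#' @param ws a [weighted_seq_set].
#' @return L x 4 matrix (columns A, C, G, T), rows summing to 1.
#' @export
position_frequency <- function(ws) {
  total <- sum(ws$counts)
  if (total < 1) stopf("zero total weight")
  L <- ws$width
  freq <- matrix(0, L, 4, dimnames = list(NULL, DNA_BASES))
  mat <- do.call(rbind, strsplit(ws$sequences, ""))
  for (b in DNA_BASES)
    freq[, b] <- colSums((mat == b) * ws$counts) / total
  freq
}

# Exact two-sided binomial P: sum of all outcome probabilities <= P(k).
#' @noRd
binom_two_sided <- function(k, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[k + 1]]))
}

#' Per-position binomial significance matrix
#'
#' For each position and base, tests the weighted base count against the
#' background frequency with an exact two-sided binomial test (sum of all
#' outcome probabilities not exceeding the observed one). Returns signed
#' `-log10(P)`: positive where the base is enriched over background,
#' negative where depleted, 0 where the observed frequency equals
#' background exactly; capped at 300. This is the "probability logo"
#' statistic scaled by statistical significance.
#'
#' @param ws a [weighted_seq_set].
#' @param background length-4 base probability vector (names A, C, G, T),
#'   strictly positive, or `"pooled"` (default: per-base frequency pooled
#'   over all positions of the weighted set) or `"uniform"`.
#' @return L x 4 signed matrix of `-log10(P)`.
#' @export
position_significance <- function(ws, background = "pooled") {
  freq <- position_frequency(ws)
  n <- sum(ws$counts)
  bg <- resolve_background(background, freq)
  sig <- freq * 0
  for (p in seq_len(nrow(freq))) for (b in DNA_BASES) {
    k <- round(freq[p, b] * n)
    if (k / n == bg[b]) { sig[p, b] <- 0; next }
    P <- binom_two_sided(k, n, bg[b])
    v <- min(-log10(P), 300)
    sig[p, b] <- if (k / n > bg[b]) v else -v
  }
  attr(sig, "background") <- bg
  sig
}

#' @noRd
resolve_background <- function(background, freq) {
  if (identical(background, "uniform")) {
    bg <- rep(0.25, 4); names(bg) <- DNA_BASES
    return(bg)
  }
  if (identical(background, "pooled")) {
    bg <- colMeans(freq)
    # guard against a base absent from the whole set
    if (any(bg <= 0)) bg <- (bg + 1e-9) / sum(bg + 1e-9)
    return(bg)
  }
  if (is.numeric(background) && length(background) == 4) {
    if (is.null(names(background))) names(background) <- DNA_BASES
    if (any(background <= 0)) stopf("background must be strictly positive")
    return(background[DNA_BASES] / sum(background))
  }
  stopf("background must be 'pooled', 'uniform', or a positive 4-vector")
}

#' Position logo (frequency + significance)
#'
#' Convenience wrapper bundling [position_frequency] and
#' [position_significance] for one weighted set.
#'
#' @inheritParams position_significance
#' @return Object of class `"position_logo"`: list with `freq`, `sig`,
#'   `background`, `n`.
#' @export
position_logo <- function(ws, background = "pooled") {
  freq <- position_frequency(ws)
  sig <- position_significance(ws, background)
  structure(list(freq = freq, sig = sig,
                 background = attr(sig, "background"), n = sum(ws$counts)),
            class = "position_logo")
}

#' @export
print.position_logo <- function(x, ...) {
  cat(sprintf("<position_logo> %d positions, total weight %d; background %s\n",
              nrow(x$freq), x$n,
              paste(sprintf("%s=%.3f", names(x$background), x$background),
                    collapse = " ")))
  invisible(x)
}

#' Consensus sequence of a logo
#'
#' `high` takes the arg-max base per position, `low` the arg-min, from
#' either the frequency matrix (`basis = "frequency"`) or the signed
#' significance matrix (`basis = "probability"`). Ties break
#' alphabetically (A < C < G < T).
#'
#' @param logo a [position_logo] (or a bare L x 4 matrix).
#' @param mode `"high"` or `"low"`.
#' @param basis `"frequency"` or `"probability"`.
#' @return DNA string of length L.
#' @export
consensus <- function(logo, mode = c("high", "low"),
                      basis = c("frequency", "probability")) {
  mode <- match.arg(mode)
  basis <- match.arg(basis)
  m <- if (inherits(logo, "position_logo")) {
    if (basis == "frequency") logo$freq else logo$sig
  } else logo
  pick <- if (mode == "high") which.max else which.min
  paste(DNA_BASES[apply(m, 1, pick)], collapse = "")
}
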