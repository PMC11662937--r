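#' Normalized suppression ratio
#'
#' The dual-luciferase screen statistic:
#' `(Nluc+/Fluc+) / (Nluc-/Fluc-)` — PTC-reporter NanoLuc over firefly
#' transfection control, with an ACE-tRNA, normalized to the same quantity
#' without one. 1 means no suppression. Per-well multiplicative factors
#' (transfection efficiency) hit both channels and cancel.
#'
#' @param nluc_plus,fluc_plus RLU with the ACE-tRNA.
#' @param nluc_minus,fluc_minus RLU of the no-tRNA control.
#' @return The ratio (vectorised).
#' @export
suppression_ratio <- function(nluc_plus, fluc_plus, nluc_minus, fluc_minus) {
  vals <- c(nluc_plus, fluc_plus, nluc_minus, fluc_minus)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("all luminescence values must be finite and > 0")
  (nluc_plus / fluc_plus) / (nluc_minus / fluc_minus)
}

#' @noRd
check_plate_frame <- function(measurements) {
  need <- c("plate_id", "well", "member_id", "nluc", "fluc", "replicate")
  if (!all(need %in% names(measurements)))
    stopf("plate table needs columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(measurements$nluc)) || any(measurements$nluc <= 0) ||
      any(!is.finite(measurements$fluc)) || any(measurements$fluc <= 0))
    stopf("nluc/fluc must be finite and > 0")
  key <- paste(measurements$plate_id, measurements$well)
  if (anyDuplicated(key))
    stopf("duplicate (plate_id, well): %s", key[duplicated(key)][1])
  invisible(measurements)
}

#' Summarize a dual-luciferase screen
#'
#' Per plate, each member well's Nluc/Fluc is normalized to that plate's
#' aggregated no-tRNA control (geometric mean of the control wells'
#' Nluc/Fluc — ratios are multiplicative, so the geometric mean is the
#' natural center). Per member, ratios are then averaged over replicates
#' with the standard error of the mean (sample sd, n-1). The control
#' itself is summarized per plate from its own aggregate, so its mean is
#' exactly 1 by construction. Plates without a control are dropped with a
#' warning.
#'
#' @param measurements data.frame of wells: `plate_id`, `well`,
#'   `member_id` (the no-tRNA control flagged by `control_id`), `nluc`,
#'   `fluc`, `replicate`; extra columns (e.g. `cell_line`) pass through
#'   unharmed.
#' @param control_id member_id marking the no-tRNA control wells.
#' @return data.frame of class `"suppression_result"`: `member_id`,
#'   `mean`, `sem`, `n` (replicates), `flagged` (fewer than 2 replicates);
#'   per-replicate ratios in the list-column `ratios`.
#' @export
summarize_library <- function(measurements, control_id = "no_tRNA") {
  check_plate_frame(measurements)
  plates <- unique(measurements$plate_id)
  ratio_rows <- list()
  for (p in plates) {
    sub <- measurements[measurements$plate_id == p, , drop = FALSE]
    ctrl <- sub$member_id == control_id
    if (!any(ctrl)) {
      warnf("plate '%s' has no '%s' control; plate dropped", p, control_id)
      next
    }
    c_ratio <- geomean(sub$nluc[ctrl] / sub$fluc[ctrl])
    memb <- sub[!ctrl, , drop = FALSE]
    ratio_rows[[length(ratio_rows) + 1L]] <- data.frame(
      member_id = c(memb$member_id, control_id),
      replicate = c(memb$replicate, min(sub$replicate[ctrl])),
      ratio = c((memb$nluc / memb$fluc) / c_ratio, 1),
      stringsAsFactors = FALSE)
  }
  if (!length(ratio_rows)) stopf("no plate with a usable control")
  rr <- do.call(rbind, ratio_rows)
  ids <- unique(rr$member_id)
  res <- data.frame(member_id = ids,
                    mean = NA_real_, sem = NA_real_, n = NA_integer_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  res$ratios <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    r <- rr$ratio[rr$member_id == ids[i]]
    res$mean[i] <- mean(r)
    res$sem[i] <- if (length(r) > 1) stats::sd(r) / sqrt(length(r)) else NA_real_
    res$n[i] <- length(r)
    res$flagged[i] <- length(r) < 2
    res$ratios[[i]] <- r
  }
  class(res) <- c("suppression_result", class(res))
  attr(res, "control_id") <- control_id
  res
}

#' Fold change versus a reference member
#'
#' Rescales summarized ratios to a reference cassette (the screens are
#' displayed relative to the parental `tRNA-Arg-TCT->UCA-3-1` cassette,
#' which maps to fold 1, white in the heat maps).
#'
#' @param results a [summarize_library] result.
#' @param reference_id member_id of the reference.
#' @return `results` with a `fold_vs_reference` column added.
#' @export
reference_normalize <- function(results, reference_id) {
  j <- match(reference_id, results$member_id)
  if (is.na(j)) stopf("reference '%s' not found in results", reference_id)
  results$fold_vs_reference <- results$mean / results$mean[j]
  results
}

#' Arrange member results as a heat-map matrix
#'
#' Fills fold-changes row-major in manifest order into a matrix with
#' `n_cols` columns, padding the tail with `NA`. Mirrors the paper-style
#' screen heat maps, where cells are individual cassettes and columns
#' carry no meaning.
#'
#' @param results a [reference_normalize] result (needs
#'   `fold_vs_reference`).
#' @param n_cols number of columns (>= 1).
#' @return numeric matrix with a `member_ids` attribute (same shape,
#'   `NA` in padding cells).
#' @export
heatmap_matrix <- function(results, n_cols) {
  if (n_cols < 1) stopf("n_cols must be >= 1")
  if (is.null(results$fold_vs_reference))
    stopf("results lack fold_vs_reference; run reference_normalize() first")
  vals <- results$fold_vs_reference
  n <- length(vals)
  n_rows <- ceiling(n / n_cols)
  m <- matrix(NA_real_, n_rows, n_cols)
  ids <- matrix(NA_character_, n_rows, n_cols)
  m[seq_len(n)] <- NA  # placeholder; fill row-major below
  for (i in seq_len(n)) {
    r <- ((i - 1) %/% n_cols) + 1
    c <- ((i - 1) %% n_cols) + 1
    m[r, c] <- vals[i]
    ids[r, c] <- results$member_id[i]
  }
  attr(m, "member_ids") <- ids
  m
}

#' @export
print.suppression_result <- function(x, ...) {
  cat(sprintf("<suppression_result> %d member(s); control '%s'\n",
              nrow(x), attr(x, "control_id")))
  print.data.frame(utils::head(
    x[, setdiff(names(x), "ratios"), drop = FALSE], 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}
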