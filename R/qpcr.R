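#' Comparative-Ct relative quantification (2^-ddCt)
#'
#' Relative quantity of a target transcript (e.g. the tRNA transcript
#' tabulator ribozyme proxy) normalized to a reference gene (e.g. TBP)
#' and a calibrator sample: `dCt = mean(Ct_target) - mean(Ct_reference)`
#' per sample, `ddCt = dCt_sample - dCt_calibrator`,
#' `RQ = 2^-ddCt`. The calibrator's RQ is exactly 1. Amplification
#' efficiency is fixed at 2, the method's defining assumption.
#'
#' @param records data.frame of Ct measurements with columns `sample_id`,
#'   `target` (`"target"`/`"reference"`, or any two labels with the
#'   reference named by `reference`), `ct` (in (0, 45)), and a logical
#'   `is_calibrator` column (or pass `calibrator`). Technical replicates
#'   are rows; at least 2 per (sample, target).
#' @param reference label in `target` marking the reference gene; by
#'   default the records' second unique label, or `"reference"` if
#'   present.
#' @param calibrator sample_id of the calibrator; alternatively flag rows
#'   with an `is_calibrator` column. Exactly one calibrator sample is
#'   required.
#' @return data.frame: `sample_id`, `dct`, `ddct`, `rq`,
#'   `n_target`, `n_reference`.
#' @export
relative_quantity <- function(records, reference = NULL, calibrator = NULL) {
  need <- c("sample_id", "target", "ct")
  if (!all(need %in% names(records)))
    stopf("records need columns %s", paste(need, collapse = ", "))
  if (any(records$ct <= 0 | records$ct >= 45))
    stopf("Ct values must lie in (0, 45)")
  labs <- unique(records$target)
  if (length(labs) != 2) stopf("need exactly 2 target labels, got %d",
                               length(labs))
  if (is.null(reference))
    reference <- if ("reference" %in% labs) "reference" else labs[2]
  if (!reference %in% labs) stopf("reference label '%s' not found", reference)
  if (is.null(calibrator)) {
    if (is.null(records$is_calibrator))
      stopf("give a calibrator sample_id or an is_calibrator column")
    calibrator <- unique(records$sample_id[records$is_calibrator])
  }
  if (length(calibrator) != 1)
    stopf("exactly one calibrator required, got %d", length(calibrator))
  samples <- unique(records$sample_id)
  if (!calibrator %in% samples) stopf("calibrator '%s' has no records",
                                      calibrator)
  dct <- vapply(samples, function(s) {
    tg <- records$ct[records$sample_id == s & records$target != reference]
    rf <- records$ct[records$sample_id == s & records$target == reference]
    if (length(tg) < 2 || length(rf) < 2)
      stopf("sample '%s' needs >= 2 technical replicates per gene", s)
    mean(tg) - mean(rf)
  }, numeric(1))
  n_t <- vapply(samples, function(s)
    sum(records$sample_id == s & records$target != reference), integer(1))
  n_r <- vapply(samples, function(s)
    sum(records$sample_id == s & records$target == reference), integer(1))
  ddct <- dct - dct[match(calibrator, samples)]
  data.frame(sample_id = samples, dct = unname(dct), ddct = unname(ddct),
             rq = 2^(-unname(ddct)), n_target = unname(n_t),
             n_reference = unname(n_r), stringsAsFactors = FALSE)
}
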