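# Canonical cloverleaf layout used by the simulator: 7-bp acceptor, 4-bp D
# stem / 8-nt D loop, 5-bp anticodon stem / 7-nt loop, 5-nt variable loop,
# 5-bp t-stem / 7-nt T loop, 4-nt 3' trailing region. 76 nt total,
# anticodon at 0-based indices 33-35.
CANONICAL_STRUCTURE <- paste0(
  "(((((((", "..",
  "((((", "........", "))))", ".",
  "(((((", ".......", ")))))",
  ".....",
  "(((((", ".......", ")))))",
  ")))))))", "....")

#' Simulation configuration
#'
#' One bundle of ground-truth parameters for every simulator in the
#' package. Defaults emulate the study conditions of the dual-luciferase
#' cassette screens: 55-bp 5' UCEs and 35-bp 3' trailers, six independent
#' transfections per member, ~10% multiplicative channel noise with
#' substantial per-well transfection-efficiency variation, a saturating
#' dose-response with `sup_max = 40` and `dd50 = 8` ng/ul over an 8-dose
#' 2-fold dilution series, 98% cognate amino-acid incorporation, and
#' 2-fold transcript differences on the qPCR side.
#'
#' @param seed integer master seed; every simulator derives its RNG state
#'   from it, so outputs are byte-identical across runs.
#' @param n_genes number of tRNA genes planted in the toy genome.
#' @param n_dup_flanks how many genes reuse gene 1's 5' flank (dedup
#'   tests).
#' @param flank5_len,flank3_len flank lengths (bp) guaranteed around each
#'   gene.
#' @param plate_cv per-channel lognormal coefficient of variation.
#' @param te_sigma lognormal sigma of per-well transfection efficiency
#'   (multiplies both channels).
#' @param n_replicates independent transfections per member.
#' @param doses dose grid, ng/ul.
#' @param sup_max,dd50 true dose-response parameters.
#' @param dose_cv lognormal CV of dose-response ratios.
#' @param incorporation named true incorporation fractions (sum 1).
#' @param ionization named per-amino-acid ionization factors.
#' @param ms_cv lognormal CV of MS abundances.
#' @param qpcr_log2fc named true log2 fold-changes vs the calibrator
#'   (calibrator added implicitly at 0).
#' @param ct_sd Gaussian sd of technical-replicate Ct values.
#' @return Object of class `"sim_config"` (a named list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 30L, n_dup_flanks = 3L,
                       flank5_len = 55L, flank3_len = 35L,
                       plate_cv = 0.1, te_sigma = 0.5, n_replicates = 6L,
                       doses = c(0.39, 0.78, 1.56, 3.125, 6.25, 12.5, 25, 50),
                       sup_max = 40, dd50 = 8, dose_cv = 0.1,
                       incorporation = c(R = 0.98, K = 0.01, W = 0.01),
                       ionization = c(R = 1, K = 3, W = 0.4),
                       ms_cv = 0,
                       qpcr_log2fc = c(high = 2, medium = 0, low = -2),
                       ct_sd = 0.1) {
  stopifnot(n_genes >= 1, flank5_len >= 1, flank3_len >= 1,
            plate_cv >= 0, te_sigma >= 0, dose_cv >= 0, ms_cv >= 0,
            ct_sd >= 0, dd50 > 0, sup_max >= 1)
  if (n_dup_flanks >= n_genes) stopf("n_dup_flanks must be < n_genes")
  if (abs(sum(incorporation) - 1) > 1e-9)
    stopf("incorporation fractions must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> seed %d; %d genes; plate CV %.2g, ",
                     "TE sigma %.2g, %d reps; sup_max %.3g, dd50 %.3g\n"),
              x$seed, x$n_genes, x$plate_cv, x$te_sigma, x$n_replicates,
              x$sup_max, x$dd50))
  invisible(x)
}

#' @noRd
random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                collapse = "")

#' Random canonical tRNA body
#'
#' Draws a 76-nt body matching the simulator's canonical cloverleaf:
#' loops are random, stem 3' strands complement their 5' strands (no
#' wobbles), and the anticodon triplet can be pinned.
#'
#' @param anticodon optional DNA 3-mer to place at the anticodon.
#' @return list with `body` and `structure`.
#' @export
sim_trna_body <- function(anticodon = NULL) {
  db <- strsplit(CANONICAL_STRUCTURE, "")[[1]]
  n <- length(db)
  b <- character(n)
  unpaired <- which(db == ".")
  b[unpaired] <- sample(DNA_BASES, length(unpaired), replace = TRUE)
  pairs <- match_brackets(CANONICAL_STRUCTURE)
  b[pairs[, 1] + 1L] <- sample(DNA_BASES, nrow(pairs), replace = TRUE)
  b[pairs[, 2] + 1L] <- comp_base(b[pairs[, 1] + 1L])
  if (!is.null(anticodon)) b[34:36] <- strsplit(anticodon, "")[[1]]
  list(body = paste(b, collapse = ""), structure = CANONICAL_STRUCTURE)
}

#' Simulate a toy genome with planted tRNA genes
#'
#' Plants `n_genes` canonical-cloverleaf tRNA genes on both strands of two
#' toy chromosomes, each with known 5'/3' flanks; `n_dup_flanks` genes
#' reuse gene 1's 5' flank so flank deduplication has a known answer.
#' Deterministic per seed.
#'
#' @param cfg a [sim_config].
#' @return list: `genome` (named character vector of chromosome
#'   sequences), `bed` (BED6-style data.frame, 0-based half-open),
#'   `structures` (data.frame `gene_id`, `structure`), `truth`
#'   (data.frame per gene: `gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `body`, `flank5`, `flank3`).
#' @export
sim_genome <- function(cfg) {
  with_seed(cfg$seed + 101L, {
    pad <- 20L
    n <- cfg$n_genes
    chroms <- rep(c("chr1", "chr2"), length.out = n)
    strands <- rep(c("+", "-"), length.out = n)
    dup_genes <- if (cfg$n_dup_flanks > 0)
      1L + seq_len(cfg$n_dup_flanks) else integer(0)
    truth <- NULL
    parts <- list(chr1 = character(0), chr2 = character(0))
    offsets <- c(chr1 = 0L, chr2 = 0L)
    flank5_1 <- NULL
    for (g in seq_len(n)) {
      bd <- sim_trna_body()
      f5 <- random_dna(cfg$flank5_len)
      if (g == 1L) flank5_1 <- f5
      if (g %in% dup_genes) f5 <- flank5_1
      f3 <- random_dna(cfg$flank3_len)
      # the trailer the cassette libraries expect: Pol III poly-T up front
      substr(f3, 5, 11) <- "TTTTTTT"
      cassette <- paste0(f5, bd$body, f3)
      chrom <- chroms[g]; strand <- strands[g]
      seg <- if (strand == "+") cassette else revcomp(cassette)
      lead <- random_dna(pad)
      body_off <- if (strand == "+") cfg$flank5_len else cfg$flank3_len
      start <- offsets[chrom] + pad + body_off
      end <- start + nchar(bd$body)
      parts[[chrom]] <- c(parts[[chrom]], lead, seg)
      offsets[chrom] <- offsets[chrom] + pad + nchar(seg)
      truth <- rbind(truth, data.frame(
        gene_id = sprintf("synth-tRNA-%02d", g), chrom = chrom,
        start = start, end = end, strand = strand, body = bd$body,
        flank5 = f5, flank3 = f3, stringsAsFactors = FALSE))
    }
    tailpad <- random_dna(pad)
    genome <- vapply(parts, function(p) paste(c(p, tailpad), collapse = ""),
                     character(1))
    bed <- data.frame(chrom = truth$chrom, start = truth$start,
                      end = truth$end, name = truth$gene_id, score = 0L,
                      strand = truth$strand, stringsAsFactors = FALSE)
    structures <- data.frame(gene_id = truth$gene_id,
                             structure = CANONICAL_STRUCTURE,
                             stringsAsFactors = FALSE)
    list(genome = genome, bed = bed, structures = structures, truth = truth)
  })
}

#' Simulate dual-luciferase plates
#'
#' One plate per replicate, each holding every member plus no-tRNA control
#' wells. Per well, a lognormal transfection-efficiency factor multiplies
#' both channels (and therefore cancels from every ratio); each channel
#' additionally carries independent lognormal noise with CV
#' `cfg$plate_cv`. With both noise sources at 0 the estimated ratios are
#' exactly the true ones.
#'
#' @param cfg a [sim_config].
#' @param true_ratios named numeric vector: true suppression ratio per
#'   member.
#' @param n_controls no-tRNA control wells per plate.
#' @return data.frame of wells (`plate_id`, `well`, `member_id`, `nluc`,
#'   `fluc`, `cell_line`, `replicate`) with the truth attached as
#'   attribute `truth`.
#' @export
sim_plates <- function(cfg, true_ratios, n_controls = 4L) {
  if (is.null(names(true_ratios))) stopf("true_ratios must be named")
  with_seed(cfg$seed + 202L, {
    sdlog <- sqrt(log(1 + cfg$plate_cv^2))
    base_nluc <- 1e3; base_fluc <- 1e5
    rows <- list()
    for (rep_i in seq_len(cfg$n_replicates)) {
      ids <- c(names(true_ratios), rep("no_tRNA", n_controls))
      tr <- c(unname(true_ratios), rep(1, n_controls))
      nw <- length(ids)
      wells <- if (nw <= 96) {
        paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))[seq_len(nw)]
      } else sprintf("W%04d", seq_len(nw))
      te <- stats::rlnorm(nw, 0, cfg$te_sigma)
      noise_n <- stats::rlnorm(nw, 0, sdlog)
      noise_f <- stats::rlnorm(nw, 0, sdlog)
      rows[[rep_i]] <- data.frame(
        plate_id = sprintf("plate%02d", rep_i), well = wells,
        member_id = ids,
        nluc = base_nluc * tr * te * noise_n,
        fluc = base_fluc * te * noise_f,
        cell_line = "16HBE14o-", replicate = rep_i,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- true_ratios
    out
  })
}

#' Simulate a dose-response dataset
#'
#' Ratios follow [dose_model] at the config's true `sup_max`/`dd50` with
#' multiplicative lognormal noise of CV `cfg$dose_cv`, `n_replicates`
#' replicates per dose.
#'
#' @param cfg a [sim_config].
#' @return data.frame (`dose`, `ratio`, `replicate`) with attribute
#'   `truth = c(sup_max, dd50)`.
#' @export
sim_dose <- function(cfg) {
  with_seed(cfg$seed + 303L, {
    sdlog <- sqrt(log(1 + cfg$dose_cv^2))
    grid <- expand.grid(dose = cfg$doses,
                        replicate = seq_len(cfg$n_replicates))
    mu <- dose_model(grid$dose, cfg$sup_max, cfg$dd50)
    out <- data.frame(dose = grid$dose,
                      ratio = mu * stats::rlnorm(nrow(grid), 0, sdlog),
                      replicate = grid$replicate)
    attr(out, "truth") <- c(sup_max = cfg$sup_max, dd50 = cfg$dd50)
    out
  })
}

#' Simulate targeted-MS abundance tables
#'
#' The equimolar control's abundance for each amino acid is its
#' ionization factor (times a common scale); the sample's is its true
#' incorporation fraction times that factor. Both carry lognormal noise
#' of CV `cfg$ms_cv` (0 by default: the generative model then matches the
#' correction exactly).
#'
#' @param cfg a [sim_config].
#' @return list: `control`, `sample` (named abundance vectors), `truth`
#'   (named true fractions).
#' @export
sim_ms <- function(cfg) {
  with_seed(cfg$seed + 404L, {
    aa <- names(cfg$incorporation)
    if (!all(aa %in% names(cfg$ionization)))
      stopf("every incorporated amino acid needs an ionization factor")
    ion <- cfg$ionization[aa]
    sdlog <- if (cfg$ms_cv > 0) sqrt(log(1 + cfg$ms_cv^2)) else 0
    base <- 1e6
    noise <- function(k) if (sdlog > 0) stats::rlnorm(k, 0, sdlog) else 1
    control <- base * ion * noise(length(aa))
    samp <- base * cfg$incorporation * ion * noise(length(aa))
    names(control) <- aa; names(samp) <- aa
    list(control = control, sample = samp, truth = cfg$incorporation)
  })
}

#' Simulate comparative-Ct qPCR records
#'
#' One calibrator sample plus one sample per entry of `cfg$qpcr_log2fc`;
#' target Ct values shift by `-log2fc` cycles relative to the calibrator
#' while reference Ct stays put, so the true RQ is `2^log2fc`. Triplicate
#' technical replicates with Gaussian noise `cfg$ct_sd`.
#'
#' @param cfg a [sim_config].
#' @return data.frame (`sample_id`, `target`, `ct`, `is_calibrator`) with
#'   attribute `truth` (named true RQs, calibrator = 1).
#' @export
sim_qpcr <- function(cfg) {
  with_seed(cfg$seed + 505L, {
    base_t <- 24; base_r <- 20
    samples <- c(calibrator = 0, cfg$qpcr_log2fc)
    rows <- list()
    for (s in names(samples)) {
      rows[[s]] <- data.frame(
        sample_id = s,
        target = rep(c("TTT", "TBP"), each = 3),
        ct = c(stats::rnorm(3, base_t - samples[s], cfg$ct_sd),
               stats::rnorm(3, base_r, cfg$ct_sd)),
        is_calibrator = s == "calibrator",
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    truth <- 2^samples
    names(truth) <- names(samples)
    attr(out, "truth") <- truth
    out
  })
}

#' Write every simulated input to disk
#'
#' Materialises the full synthetic study: genome FASTA + BED6 + structure
#' TSV, plate CSV, dose CSV, MS control/sample CSVs, qPCR CSV, and a
#' `truth.json` sidecar holding every ground-truth value.
#'
#' @param cfg a [sim_config].
#' @param outdir output directory (created if missing).
#' @param true_ratios named member ratios for the plate simulator;
#'   defaults to a small three-member screen.
#' @return Invisibly, the list of file paths written.
#' @export
simulate_all <- function(cfg, outdir,
                         true_ratios = c(m_low = 0.5, m_mid = 1,
                                         m_high = 4)) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  gen <- sim_genome(cfg)
  fa <- Biostrings::DNAStringSet(gen$genome)
  Biostrings::writeXStringSet(fa, p("genome.fasta"))
  utils::write.table(gen$bed, p("genes.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(gen$structures, p("structures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  plates <- sim_plates(cfg, true_ratios)
  utils::write.csv(plates, p("plates.csv"), row.names = FALSE)
  dose <- sim_dose(cfg)
  utils::write.csv(dose, p("dose.csv"), row.names = FALSE)
  ms <- sim_ms(cfg)
  utils::write.csv(data.frame(aa = names(ms$control),
                              abundance = unname(ms$control)),
                   p("ms_control.csv"), row.names = FALSE)
  utils::write.csv(data.frame(aa = names(ms$sample),
                              abundance = unname(ms$sample)),
                   p("ms_sample.csv"), row.names = FALSE)
  qp <- sim_qpcr(cfg)
  utils::write.csv(qp, p("qpcr.csv"), row.names = FALSE)
  truth <- list(
    genes = gen$truth,
    plate_ratios = as.list(true_ratios),
    dose = as.list(attr(dose, "truth")),
    incorporation = as.list(ms$truth),
    qpcr_rq = as.list(attr(qp, "truth")))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(vapply(c("genome.fasta", "genes.bed", "structures.tsv",
                     "plates.csv", "dose.csv", "ms_control.csv",
                     "ms_sample.csv", "qpcr.csv", "truth.json"),
                   p, character(1)))
}
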