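test_that("gene bodies come from the genome in transcriptional sense", {
  genome <- c(chr1 = "AAACGTAAGTTT")
  bed <- data.frame(chrom = "chr1", start = 3L, end = 9L,
                    name = c("g_plus"), score = 0L, strand = "+")
  f_bed <- withr::local_tempfile(fileext = ".bed")
  write.table(bed, f_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  recs <- parse_trna_genes(f_bed, genome)
  expect_equal(recs[[1]]$body_seq, "CGTAAG")

  bed$strand <- "-"; bed$name <- "g_minus"
  write.table(bed, f_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  recs <- parse_trna_genes(f_bed, genome)
  expect_equal(recs[[1]]$body_seq, "CTTACG")
})

test_that("bad annotations are rejected with informative errors", {
  genome <- c(chr1 = "ACGTACGTAC")
  f_bed <- withr::local_tempfile(fileext = ".bed")
  bed <- data.frame(chrom = "chr1", start = 2L, end = 20L, name = "far",
                    score = 0L, strand = "+")
  write.table(bed, f_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(parse_trna_genes(f_bed, genome), "out of chromosome range")

  bed <- data.frame(chrom = "chrX", start = 0L, end = 4L, name = "nochr",
                    score = 0L, strand = "+")
  write.table(bed, f_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(parse_trna_genes(f_bed, genome), "missing from genome")

  bed <- data.frame(chrom = "chr1", start = c(0L, 4L), end = c(4L, 8L),
                    name = "dup", score = 0L, strand = "+")
  write.table(bed, f_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  expect_error(parse_trna_genes(f_bed, genome), "duplicate gene_id")
})

test_that("simulated genome round-trips: extract, relocate, same coords", {
  cfg <- sim_config(seed = 11, n_genes = 12)
  gen <- sim_genome(cfg)
  f_bed <- withr::local_tempfile(fileext = ".bed")
  write.table(gen$bed, f_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  recs <- parse_trna_genes(f_bed, gen$genome, gen$structures)
  expect_length(recs, 12)
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    expect_equal(r$body_seq, gen$truth$body[i])
    # relocate by exact search of the genomic-strand sequence
    gseq <- if (r$strand == "+") r$body_seq
            else as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(r$body_seq)))
    hit <- regexpr(gseq, gen$genome[[r$chrom]], fixed = TRUE)
    expect_equal(as.integer(hit) - 1L, r$start)
  }
})

test_that("canonical cloverleaf anatomy: 7/4/5/5 stems, anticodon 33-35", {
  rec <- canon_record()
  cl <- build_cloverleaf(rec)
  expect_equal(nrow(cl$acceptor_stem), 7)
  expect_equal(nrow(cl$d_stem), 4)
  expect_equal(nrow(cl$ac_stem), 5)
  expect_equal(nrow(cl$t_stem), 5)
  expect_equal(cl$anticodon, 33:35)
  expect_length(cl$loops$ac_loop, 7)
  expect_equal(cl$ac_loop_flank, c(31L, 32L, 36L, 37L))
  # t-stem pair labels 49-65, 50-64, 51-63 are the outermost three
  expect_equal(cl$tstem_pairs_49_51, cl$t_stem[1:3, ])
  # 3' trailing overhang labelled explicitly
  expect_equal(cl$loops$trailing, 72:75)
})

test_that("reported pairs equal a stack-based oracle; partition holds", {
  rec <- canon_record()
  cl <- build_cloverleaf(rec)
  expect_equal(unname(cloverleaf_pairs(cl)), unname(oracle_pairs(CANON_DB)))
  # stems + loops/linkers/trailing partition every body index exactly once
  idx <- c(as.vector(cloverleaf_pairs(cl)), unlist(cl$loops, use.names = FALSE))
  expect_equal(sort(idx), 0:(nchar(rec$body_seq) - 1))
})

test_that("build_cloverleaf is deterministic and rejects malformed input", {
  rec <- canon_record()
  expect_identical(build_cloverleaf(rec), build_cloverleaf(rec))
  # 9-nt anticodon loop
  db_bad <- sub("\\(\\(\\(\\(\\(\\.{7}\\)\\)\\)\\)\\)",
                "(((((.........)))))", CANON_DB)
  body <- body_from_structure(db_bad, rep("G", nrow(oracle_pairs(db_bad))))
  expect_error(
    build_cloverleaf(list(body_seq = body, structure = db_bad)),
    "anticodon loop")
  # unbalanced
  expect_error(
    build_cloverleaf(list(body_seq = "ACGT", structure = "((..")),
    "unbalanced")
  # three helices only
  db3 <- "((((....((((....))))..((((....))))....))))"
  body3 <- body_from_structure(db3, rep("G", nrow(oracle_pairs(db3))))
  expect_error(
    build_cloverleaf(list(body_seq = body3, structure = db3)),
    "4 helices")
})

test_that("G-T wobble pairs are flagged, other mismatches rejected", {
  rec <- canon_record()
  b <- rec$body_seq
  cl0 <- build_cloverleaf(rec)
  i <- cl0$acceptor_stem[1, 1] + 1; j <- cl0$acceptor_stem[1, 2] + 1
  substr(b, i, i) <- "G"; substr(b, j, j) <- "T"
  cl <- build_cloverleaf(list(body_seq = b, structure = CANON_DB))
  expect_equal(nrow(cl$wobble_pairs), 1)
  substr(b, i, i) <- "A"; substr(b, j, j) <- "C"
  expect_error(build_cloverleaf(list(body_seq = b, structure = CANON_DB)),
               "non-complementary")
})
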