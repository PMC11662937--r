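test_that("anticodon editing targets each stop codon and is idempotent", {
  rec <- canon_record()
  cl <- build_cloverleaf(rec)
  for (case in list(c("TGA", "TCA"), c("TAG", "CTA"), c("TAA", "TTA"))) {
    b <- edit_anticodon(cl, rec$body_seq, case[1])
    expect_equal(substr(b, 34, 36), case[2])
    # untouched outside the anticodon triplet
    ch_b <- strsplit(b, "")[[1]]; ch_0 <- strsplit(rec$body_seq, "")[[1]]
    expect_equal(which(ch_b != ch_0) %in% 34:36, rep(TRUE, sum(ch_b != ch_0)))
    expect_identical(edit_anticodon(cl, b, case[1]), b)
  }
  expect_error(edit_anticodon(cl, rec$body_seq, "TGG"), "not a stop codon")
})

test_that("flank extraction is strand-aware, deduplicated, in-genome", {
  cfg <- sim_config(seed = 5, n_genes = 12, n_dup_flanks = 3)
  gen <- sim_genome(cfg)
  f_bed <- withr::local_tempfile(fileext = ".bed")
  write.table(gen$bed, f_bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  recs <- parse_trna_genes(f_bed, gen$genome, gen$structures)
  fl5 <- extract_flanks(recs, gen$genome, 5, cfg$flank5_len)
  expect_equal(nrow(fl5), 12 - 3)        # 3 engineered duplicates collapse
  expect_false(anyDuplicated(fl5$flank) > 0)
  expect_setequal(fl5$flank, unique(gen$truth$flank5))
  # provenance: the duplicated flank keeps its first carrier
  dup_fl <- gen$truth$flank5[1]
  expect_equal(fl5$gene_id[fl5$flank == dup_fl], gen$truth$gene_id[1])
  expect_equal(fl5$n_dup[fl5$flank == dup_fl], 4L)  # gene 1 + 3 copies

  # minus-strand 5' flank is the reverse complement of the window
  # genomically downstream of the gene (pick one outside the planted
  # duplicate-flank set, whose provenance collapses onto gene 1)
  minus_i <- setdiff(which(gen$truth$strand == "-"), 2:4)[1]
  minus <- recs[[minus_i]]
  win <- substr(gen$genome[[minus$chrom]], minus$end + 1,
                minus$end + cfg$flank5_len)
  expect_equal(
    fl5$flank[fl5$gene_id == minus$gene_id],
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(win))))

  fl3 <- extract_flanks(recs, gen$genome, 3, cfg$flank3_len)
  expect_setequal(fl3$flank, unique(gen$truth$flank3))
  # out-of-range flanks skip the gene with a warning
  expect_warning(long <- extract_flanks(recs, gen$genome, 5, 10000),
                 "skipped")
  expect_equal(nrow(long), 0)
})

test_that("saturation libraries enumerate 4^k members lexicographically", {
  tpl <- "ACGTACGT"
  for (k in 0:4) {
    lib <- enumerate_saturation(tpl, seq_len(k) - 1L)
    expect_length(lib, 4^k)
    # brute-force oracle: nested expansion
    if (k > 0) {
      kmers <- vapply(lib, function(m)
        paste(strsplit(m$seq, "")[[1]][seq_len(k)], collapse = ""),
        character(1))
      oracle <- sort(apply(
        do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k)),
        1, paste, collapse = ""))
      expect_equal(kmers, unname(oracle))
    }
    expect_equal(sum(vapply(lib, `[[`, logical(1), "original")), 1)
    # member round-trip from parent + edits
    for (m in lib[c(1, length(lib))])
      expect_equal(apply_edits(tpl, m), m$seq)
  }
  expect_error(enumerate_saturation(tpl, c(1, 1)), "duplicate")
})

test_that("sticky-stem sites match hand enumeration and give 2^k members", {
  fx <- sticky_fixture(3)
  lib <- design_sticky_stem_library(fx$target, fx$family)
  expect_equal(nrow(lib$sites), 3)
  # hand-known site identities: the pairs the family flipped to C-G
  pr <- oracle_pairs(CANON_DB)
  expect_equal(lib$sites$i, pr[fx$sites, 1])
  expect_equal(lib$sites$j, pr[fx$sites, 2])
  expect_true(all(lib$sites$library_pair == "CG"))
  expect_length(lib$members, 8)
  # each member differs from the parent at exactly its bitmask's pairs
  for (mask in 0:7) {
    m <- lib$members[[mask + 1]]
    ed <- m$edits
    want <- as.integer(sort(unlist(lapply(
      which(bitwAnd(mask, 2^(0:2)) > 0),
      function(s) c(lib$sites$i[s], lib$sites$j[s])))))
    expect_equal(as.integer(sort(ed$position)), want)
    expect_equal(apply_edits(fx$target$body, m), m$seq)
  }
  # family identical to target: no sites, library = {original}
  same <- list(body = fx$target$body, cl = fx$target$cl)
  expect_warning(lib0 <- design_sticky_stem_library(fx$target, list(same)),
                 "no qualifying")
  expect_length(lib0$members, 1)
  expect_true(lib0$members[[1]]$original)
})

test_that("t-stem swaps substitute both strands of pairs 49-65/50-64/51-63", {
  rec <- canon_record()
  cl <- build_cloverleaf(rec)
  b <- strsplit(rec$body_seq, "")[[1]]
  orig <- data.frame(
    variant_id = "orig",
    p49 = b[cl$t_stem[1, 1] + 1], p65 = b[cl$t_stem[1, 2] + 1],
    p50 = b[cl$t_stem[2, 1] + 1], p64 = b[cl$t_stem[2, 2] + 1],
    p51 = b[cl$t_stem[3, 1] + 1], p63 = b[cl$t_stem[3, 2] + 1])
  # build a parent differing from TS-9 at all three pairs: A-T everywhere
  pair5 <- rep("G", 21); pair5[17:19] <- "A"   # t-stem outer pairs = A-T
  body <- body_from_structure(CANON_DB, pair5)
  cl2 <- build_cloverleaf(list(body_seq = body, structure = CANON_DB))
  ts9 <- data.frame(variant_id = "TS-9", p49 = "C", p65 = "G",
                    p50 = "C", p64 = "G", p51 = "G", p63 = "C")
  lib <- design_tstem_library(body, cl2, ts9)
  expect_equal(nrow(lib[[1]]$edits), 6)
  expect_equal(sort(lib[[1]]$edits$position),
               sort(as.vector(cl2$t_stem[1:3, ])))

  lib_orig <- design_tstem_library(rec$body_seq, cl, orig)
  expect_equal(nrow(lib_orig[[1]]$edits), 0)
  expect_true(lib_orig[[1]]$original)

  # 28 variants in -> 28 members out with stable ids
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  v28 <- do.call(rbind, lapply(1:28, function(i) {
    f <- c("A", "C", "G", "T")[1 + (i %% 4)]
    s <- c("A", "C", "G", "T")[1 + ((i %/% 4) %% 4)]
    data.frame(variant_id = sprintf("TS-%d", i),
               p49 = f, p65 = comp[f], p50 = s, p64 = comp[s],
               p51 = "G", p63 = "C")
  }))
  lib28 <- design_tstem_library(rec$body_seq, cl, v28)
  expect_length(lib28, 28)
  expect_equal(vapply(lib28, `[[`, character(1), "member_id"),
               sprintf("TS-%d", 1:28))
  # non-complementary pair rejected, wobble flagged
  bad <- ts9; bad$p65 <- "C"
  expect_error(design_tstem_library(body, cl2, bad), "non-complementary")
  wob <- ts9; wob$p49 <- "G"; wob$p65 <- "T"
  expect_true(attr(design_tstem_library(body, cl2, wob)[[1]], "wobble"))
})

test_that("golden gate oligos assemble round-trip and reject ambiguity", {
  gg <- make_golden_gate_oligos("ACGT", "AATT", "GGCC")
  expect_equal(assemble_golden_gate(gg), "AATTACGTGGCC")
  expect_error(make_golden_gate_oligos("ACGT", "AATT", "AATT"), "ambiguous")
  expect_error(make_golden_gate_oligos("ACGT", "GGCC", "GGCC"), "ambiguous")
  # palindromic pair: oh5 == revcomp(oh3)
  expect_error(make_golden_gate_oligos("ACGT", "GACC", "GGTC"), "ambiguous")
  set.seed(402)
  for (i in 1:100) {
    insert <- random_dna_str(60)
    repeat {
      oh5 <- random_dna_str(4); oh3 <- random_dna_str(4)
      rc3 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(oh3)))
      if (oh5 != oh3 && oh5 != rc3) break
    }
    gg <- make_golden_gate_oligos(insert, oh5, oh3)
    expect_equal(assemble_golden_gate(gg), paste0(oh5, insert, oh3))
  }
})

test_that("premature poly-T terminators are found; missing terminator fatal", {
  cas <- expression_cassette(strrep("A", 10), "ACGTTTTTACG", "GACCTTTTTTT")
  w <- check_internal_terminator(cas)
  expect_equal(nrow(w), 1)
  expect_equal(w$position, 13)   # the body's TTTTT run, 0-based
  expect_equal(w$runlength, 5)
  expect_equal(unname(attr(w, "terminator")["position"]), 10 + 11 + 4)

  clean <- expression_cassette(strrep("A", 10), "ACGTACG", "GACCTTTTTTT")
  expect_equal(nrow(check_internal_terminator(clean)), 0)
  expect_error(expression_cassette("AAAA", "ACGT", "GACCTTT"),
               "terminator")
})

test_that("synthetic-accessibility filter rejects homopolymers and GC extremes", {
  ok <- paste0(strrep("ACGT", 20))
  bad_homo <- paste0(strrep("A", 20), strrep("ACGT", 15))
  bad_gc <- strrep("GC", 40)
  expect_equal(synthetically_accessible(c(ok, bad_homo, bad_gc)),
               c(TRUE, FALSE, FALSE))
})

test_that("library manifest reconstructs members from parent + edits", {
  tpl <- "ACGTACGTAC"
  lib <- enumerate_saturation(tpl, c(2L, 5L), library_class = "trailer4")
  man <- library_manifest(lib)
  expect_equal(nrow(man), 16)
  expect_true(all(man$library_class == "trailer4"))
  set.seed(77)
  for (i in sample(nrow(man), 5))
    expect_equal(apply_edits(tpl, lib[[i]]), man$seq[i])
})
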