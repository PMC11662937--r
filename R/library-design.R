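#' Expression cassette
#'
#' A full RNA-polymerase-III cassette: 5' upstream control element (UCE),
#' tRNA body, and 3' trailer. The trailer must contain a poly-T run of at
#' least four thymidines on the coding strand — the Pol III terminator.
#'
#' @param uce5 DNA string, the 5' UCE (e.g. the 55 bp upstream of the gene).
#' @param body DNA string, the tRNA body.
#' @param trailer3 DNA string, the 3' trailer including the terminator.
#' @param label free-text label.
#' @return Object of class `"expression_cassette"`.
#' @export
expression_cassette <- function(uce5, body, trailer3, label = "") {
  for (part in list(uce5, body, trailer3))
    if (!is_dna(part)) stopf("cassette parts must be plain ACGT DNA")
  if (!grepl("TTTT", trailer3, fixed = TRUE))
    stopf("trailer3 lacks a >=4-T Pol III terminator run")
  structure(list(uce5 = uce5, body = body, trailer3 = trailer3,
                 label = label),
            class = "expression_cassette")
}

#' @export
print.expression_cassette <- function(x, ...) {
  cat(sprintf("<expression_cassette> %s  UCE %d nt | body %d nt | trailer %d nt\n",
              x$label, nchar(x$uce5), nchar(x$body), nchar(x$trailer3)))
  invisible(x)
}

#' Full cassette sequence
#' @param x an [expression_cassette].
#' @return DNA string `uce5 + body + trailer3`.
#' @export
cassette_seq <- function(x) paste0(x$uce5, x$body, x$trailer3)

# A single library member: parent body/cassette plus its edits.
#' @noRd
library_member <- function(member_id, seq, edits, library_class,
                           original = FALSE) {
  structure(list(member_id = member_id, seq = seq, edits = edits,
                 library_class = library_class, original = original),
            class = "library_member")
}

#' @export
print.library_member <- function(x, ...) {
  cat(sprintf("<library_member> %s [%s]%s  %d edit(s)\n", x$member_id,
              x$library_class, if (x$original) " (original)" else "",
              nrow(x$edits)))
  invisible(x)
}

#' Reapply a member's edits to its parent sequence
#'
#' Round-trip identity check: applying `edits` (`position`, `from`, `to`,
#' 0-based) to the parent must reproduce the member sequence exactly.
#'
#' @param parent parent DNA string.
#' @param member a library member (from any `design_*`/`enumerate_*`
#'   function).
#' @return The reconstructed DNA string.
#' @export
apply_edits <- function(parent, member) {
  b <- strsplit(parent, "")[[1]]
  ed <- member$edits
  if (nrow(ed)) for (r in seq_len(nrow(ed))) {
    i <- ed$position[r] + 1L
    if (b[i] != ed$from[r])
      stopf("edit %d: parent has %s at %d, edit expects %s",
            r, b[i], ed$position[r], ed$from[r])
    b[i] <- ed$to[r]
  }
  paste(b, collapse = "")
}

#' @noRd
edits_frame <- function(position = integer(0), from = character(0),
                        to = character(0)) {
  # manual data.frame construction: called once per library member
  structure(list(position = as.integer(position),
                 from = as.character(from), to = as.character(to)),
            class = "data.frame",
            row.names = .set_row_names(length(position)))
}

# Build an edits frame for positions where child differs from parent.
#' @noRd
diff_edits <- function(parent, child) {
  pb <- strsplit(parent, "")[[1]]; cb <- strsplit(child, "")[[1]]
  idx <- which(pb != cb)
  edits_frame(idx - 1L, pb[idx], cb[idx])
}

#' Re-target a tRNA anticodon to a stop codon
#'
#' Replaces the anticodon triplet with the reverse complement of the stop
#' codon (DNA sense of the mRNA coding strand): `TGA -> TCA`,
#' `TAG -> CTA`, `TAA -> TTA`. This is the anticodon edit that converts a
#' natural tRNA into a nonsense suppressor (ACE-tRNA).
#'
#' @param cl cloverleaf of the body ([build_cloverleaf]).
#' @param body DNA string of the tRNA body.
#' @param stop_codon one of `"TGA"`, `"TAG"`, `"TAA"`.
#' @return The edited body DNA string.
#' @export
edit_anticodon <- function(cl, body, stop_codon) {
  if (!stop_codon %in% c("TGA", "TAG", "TAA"))
    stopf("'%s' is not a stop codon (TGA/TAG/TAA)", stop_codon)
  anti <- revcomp(stop_codon)
  b <- strsplit(body, "")[[1]]
  b[cl$anticodon + 1L] <- strsplit(anti, "")[[1]]
  paste(b, collapse = "")
}

#' Extract unique flanking sequences of tRNA genes
#'
#' Pulls the 5' UCE or 3' trailer of every gene from the genome, always in
#' the tRNA's transcriptional sense (for a minus-strand gene the 5' flank
#' is genomically downstream and is reverse-complemented). Exact duplicate
#' sequences are collapsed, keeping the first occurrence's gene as
#' provenance; genes whose flank would run off the chromosome are skipped
#' with a warning.
#'
#' @param genes list of [trna_gene_record].
#' @param genome FASTA path, `DNAStringSet`, or named character vector.
#' @param side `5` (upstream UCE) or `3` (downstream trailer).
#' @param length flank length in bp (55 and 35 are the screen's classes;
#'   850 gives the long-UCE class).
#' @return data.frame with columns `gene_id` (provenance of first
#'   occurrence), `flank` (DNA), `n_dup` (how many genes carried it), plus
#'   attribute `skipped` naming any skipped genes.
#' @export
extract_flanks <- function(genes, genome, side, length) {
  if (!side %in% c(5, 3)) stopf("side must be 5 or 3")
  if (length < 1) stopf("length must be >= 1")
  genome <- load_genome(genome)
  ids <- character(0); seqs <- character(0); skipped <- character(0)
  for (g in genes) {
    chromlen <- nchar(genome[[g$chrom]])
    upstream <- (side == 5) == (g$strand == "+")
    if (upstream) { s <- g$start - length; e <- g$start }
    else          { s <- g$end;            e <- g$end + length }
    if (s < 0 || e > chromlen) {
      skipped <- c(skipped, g$gene_id)
      next
    }
    fl <- substr(genome[[g$chrom]], s + 1L, e)
    if (g$strand == "-") fl <- revcomp(fl)
    ids <- c(ids, g$gene_id); seqs <- c(seqs, fl)
  }
  if (length(skipped))
    warnf("skipped %d gene(s) with out-of-range flanks: %s",
          length(skipped), paste(skipped, collapse = ", "))
  first <- !duplicated(seqs)
  out <- data.frame(gene_id = ids[first], flank = seqs[first],
                    n_dup = as.integer(table(factor(seqs, levels = seqs[first]))),
                    stringsAsFactors = FALSE)
  attr(out, "skipped") <- skipped
  out
}

#' Saturation mutagenesis library
#'
#' Enumerates every combination of A/C/G/T at the given template positions
#' — the design behind the 256-member 4-bp 3' trailer library and the
#' 256-member anticodon-loop (Sprinzl 32/33/37/38) library. Members are
#' ordered lexicographically by the substituted k-mer so heat-map layouts
#' are reproducible.
#'
#' @param template parent DNA string.
#' @param positions 0-based positions to saturate (distinct).
#' @param library_class label stored on each member.
#' @return list of `4^k` library members; the member equal to the template
#'   is flagged `original`.
#' @export
enumerate_saturation <- function(template, positions,
                                 library_class = "saturation") {
  positions <- as.integer(positions)
  if (anyDuplicated(positions)) stopf("duplicate positions")
  if (length(positions) &&
      (min(positions) < 0 || max(positions) >= nchar(template)))
    stopf("positions out of template range")
  k <- length(positions)
  kmers <- ""
  if (k > 0) {
    grid <- do.call(expand.grid,
                    c(rep(list(DNA_BASES), k),
                      list(stringsAsFactors = FALSE)))
    kmers <- sort(do.call(paste0, grid))
  }
  b0 <- strsplit(template, "")[[1]]
  ref <- b0[positions + 1L]
  lapply(seq_along(kmers), function(i) {
    b <- b0
    sub <- if (k > 0) strsplit(kmers[i], "")[[1]] else character(0)
    if (k > 0) b[positions + 1L] <- sub
    seq <- paste(b, collapse = "")
    changed <- which(sub != ref)
    library_member(
      member_id = if (k > 0) sprintf("%s_%s", library_class, kmers[i])
                  else sprintf("%s_original", library_class),
      seq = seq,
      edits = edits_frame(positions[changed], ref[changed], sub[changed]),
      library_class = library_class, original = length(changed) == 0)
  })
}

# Stem pair positions of a cloverleaf with a stem label, ordered by stem
# then outermost pair first.
#' @noRd
stem_sites <- function(cl) {
  stems <- list(acceptor = cl$acceptor_stem, d = cl$d_stem,
                ac = cl$ac_stem, t = cl$t_stem)
  do.call(rbind, lapply(names(stems), function(s) {
    m <- stems[[s]]
    data.frame(stem = s, i = m[, 1], j = m[, 2], stringsAsFactors = FALSE)
  }))
}

#' @noRd
pair_at <- function(body, i, j) {
  paste0(substr(body, i + 1L, i + 1L), substr(body, j + 1L, j + 1L))
}

#' "Sticky stem" combinatorial library
#'
#' Stabilises a tRNA by swapping stem pairs for C-G/G-C at positions where
#' functional isoacceptor family members do so. A site qualifies when (a)
#' the pair is not identical across target and family at that stem
#' position and (b) at least one family member carries `CG` or `GC`
#' there; the introduced pair is that member's (first in input order on
#' ties). The library is every combination of original-vs-library pair
#' over the k sites (2^k members, both strands of a pair substituted
#' jointly).
#'
#' @param target list with elements `body` (DNA) and `cl`
#'   ([build_cloverleaf] of that body).
#' @param family list of lists with elements `body` and `cl`; stems must
#'   have the same geometry as the target's.
#' @return list with `sites` (data.frame: stem, i, j, target pair, library
#'   pair, source member index) and `members` (list of `2^k` library
#'   members, `member_id` encoding the site bitmask; bit b set means site
#'   b carries the library pair).
#' @export
design_sticky_stem_library <- function(target, family) {
  tsites <- stem_sites(target$cl)
  for (f in family) {
    fs <- stem_sites(f$cl)
    if (nrow(fs) != nrow(tsites) || any(fs$stem != tsites$stem))
      stopf("family member stems not aligned to target stems")
  }
  sites <- tsites[0, ]; lib_pair <- character(0); src <- integer(0)
  for (r in seq_len(nrow(tsites))) {
    tp <- pair_at(target$body, tsites$i[r], tsites$j[r])
    fps <- vapply(seq_along(family), function(m) {
      fs <- stem_sites(family[[m]]$cl)
      pair_at(family[[m]]$body, fs$i[r], fs$j[r])
    }, character(1))
    if (all(c(tp, fps) == tp)) next          # conserved site
    hit <- which(fps %in% c("CG", "GC"))
    if (!length(hit)) next
    lp <- fps[hit[1]]
    if (lp == tp) next                       # target already sticky here
    sites <- rbind(sites, tsites[r, ])
    lib_pair <- c(lib_pair, lp); src <- c(src, hit[1])
  }
  k <- nrow(sites)
  if (k == 0) {
    warnf("no qualifying sticky-stem sites; library is the original only")
    sites_df <- data.frame(stem = character(0), i = integer(0),
                           j = integer(0), target_pair = character(0),
                           library_pair = character(0),
                           source_member = integer(0))
    mem <- library_member("sticky_0", target$body,
                          edits_frame(), "sticky_stem", original = TRUE)
    return(list(sites = sites_df, members = list(mem)))
  }
  sites_df <- data.frame(
    stem = sites$stem, i = sites$i, j = sites$j,
    target_pair = vapply(seq_len(k), function(r)
      pair_at(target$body, sites$i[r], sites$j[r]), character(1)),
    library_pair = lib_pair, source_member = src,
    stringsAsFactors = FALSE)
  b0 <- strsplit(target$body, "")[[1]]
  lp1 <- substr(lib_pair, 1, 1); lp2 <- substr(lib_pair, 2, 2)
  id_w <- nchar(as.character(2^k - 1))
  members <- lapply(0:(2^k - 1), function(mask) {
    on <- which(bitwAnd(mask, bitwShiftL(1L, 0:(k - 1))) > 0)
    b <- b0
    b[sites$i[on] + 1L] <- lp1[on]
    b[sites$j[on] + 1L] <- lp2[on]
    pos <- c(sites$i[on], sites$j[on])
    keep <- pos[b[pos + 1L] != b0[pos + 1L]]  # a strand may already match
    keep <- sort(keep)
    library_member(sprintf("sticky_%0*d", id_w, mask),
                   paste(b, collapse = ""),
                   edits_frame(keep, b0[keep + 1L], b[keep + 1L]),
                   "sticky_stem", original = mask == 0)
  })
  list(sites = sites_df, members = members)
}

#' t-stem variant library
#'
#' Swaps the outermost three t-stem pairs (Sprinzl 49-65, 50-64, 51-63;
#' optionally also 52-62 and 53-61) for each variant in a table — the
#' design of the 28-member EF1A-affinity panel whose winner is the
#' medium/high-affinity `C49-G65, C50-G64, G51-C63` stem ("TS-9").
#'
#' @param body parent tRNA body DNA.
#' @param cl cloverleaf of the body.
#' @param variants data.frame with columns `variant_id`, `p49`, `p65`,
#'   `p50`, `p64`, `p51`, `p63` and optionally `p52`, `p62`, `p53`, `p61`
#'   — single bases for each strand of each pair.
#' @return list of library members, one per variant, ids taken from
#'   `variant_id`; a variant identical to the parent t-stem is flagged
#'   `original`. Non-complementary specified pairs are an error; G-T
#'   wobbles are allowed and flagged via a `wobble` attribute.
#' @export
design_tstem_library <- function(body, cl, variants) {
  need <- c("variant_id", "p49", "p65", "p50", "p64", "p51", "p63")
  if (!all(need %in% names(variants)))
    stopf("variants table needs columns %s", paste(need, collapse = ", "))
  pair_cols <- list(c("p49", "p65"), c("p50", "p64"), c("p51", "p63"),
                    c("p52", "p62"), c("p53", "p61"))
  have <- vapply(pair_cols, function(pc) all(pc %in% names(variants)),
                 logical(1))
  pair_cols <- pair_cols[have]
  if (length(pair_cols) > nrow(cl$t_stem))
    stopf("variant table specifies more pairs than the t-stem has")
  idx <- cl$t_stem[seq_along(pair_cols), , drop = FALSE]
  members <- vector("list", nrow(variants))
  for (v in seq_len(nrow(variants))) {
    wob <- FALSE
    b <- strsplit(body, "")[[1]]
    for (p in seq_along(pair_cols)) {
      x <- toupper(variants[[pair_cols[[p]][1]]][v])
      y <- toupper(variants[[pair_cols[[p]][2]]][v])
      if (!x %in% DNA_BASES || !y %in% DNA_BASES)
        stopf("variant %s pair %d has non-ACGT base",
              variants$variant_id[v], p)
      if (comp_base(x) != y) {
        if (paste0(x, y) %in% c("GT", "TG")) wob <- TRUE
        else stopf("variant %s: non-complementary pair %s-%s",
                   variants$variant_id[v], x, y)
      }
      b[idx[p, 1] + 1L] <- x; b[idx[p, 2] + 1L] <- y
    }
    seq <- paste(b, collapse = "")
    m <- library_member(as.character(variants$variant_id[v]), seq,
                        diff_edits(body, seq), "tstem",
                        original = seq == body)
    attr(m, "wobble") <- wob
    members[[v]] <- m
  }
  members
}

#' Golden-Gate duplex oligonucleotides
#'
#' Builds the annealed oligo pair for directional Golden Gate cloning of
#' an insert with two distinct 4-nt 5' overhangs: `top = oh5 + insert`,
#' `bottom = revcomp(insert + oh3)`. Annealing the pair leaves
#' single-stranded 5' overhangs `oh5` (top) and `oh3` (in top-strand
#' sense), so ligation into a vector cut to expose the complementary
#' overhangs reconstructs `oh5 + insert + oh3`.
#'
#' @param insert insert DNA.
#' @param oh5,oh3 the two 4-nt overhangs. `oh5 == oh3` or
#'   `oh5 == revcomp(oh3)` would ligate in either orientation and is
#'   rejected.
#' @return list with `top`, `bottom`, `oh5`, `oh3`.
#' @export
make_golden_gate_oligos <- function(insert, oh5, oh3) {
  if (nchar(oh5) != 4 || nchar(oh3) != 4) stopf("overhangs must be 4 nt")
  for (x in list(insert, oh5, oh3))
    if (!is_dna(x)) stopf("insert and overhangs must be plain ACGT DNA")
  if (oh5 == oh3 || oh5 == revcomp(oh3))
    stopf("ambiguous ligation: oh5 equals oh3 or its reverse complement")
  list(top = paste0(oh5, insert), bottom = revcomp(paste0(insert, oh3)),
       oh5 = oh5, oh3 = oh3)
}

#' Simulated anneal-and-ligate of a Golden Gate duplex
#'
#' In-silico check of a [make_golden_gate_oligos] pair: verifies that the
#' two oligos anneal over the insert with the stated 5' overhangs and
#' returns the ligated product `oh5 + insert + oh3`.
#'
#' @param oligos result of [make_golden_gate_oligos].
#' @return The assembled DNA string.
#' @export
assemble_golden_gate <- function(oligos) {
  top <- oligos$top; bottom <- oligos$bottom
  insert <- substr(top, 5L, nchar(top))
  if (revcomp(substr(bottom, 5L, nchar(bottom))) != insert)
    stopf("oligos do not anneal over the insert")
  if (substr(top, 1L, 4L) != oligos$oh5)
    stopf("top oligo lacks the oh5 overhang")
  if (revcomp(substr(bottom, 1L, 4L)) != oligos$oh3)
    stopf("bottom oligo lacks the oh3 overhang")
  paste0(oligos$oh5, insert, oligos$oh3)
}

#' Scan a cassette for premature Pol III terminators
#'
#' RNA polymerase III terminates at runs of four or more thymidines, so
#' any such run upstream of the designated trailer terminator truncates
#' the transcript. Reports every maximal >=4-T run on the coding strand
#' that starts before the designated terminator (the first >=4-T run in
#' the trailer); the designated terminator itself is not a warning.
#'
#' @param cassette an [expression_cassette].
#' @return data.frame of warnings with 0-based `position` (run start in
#'   the full cassette) and `runlength`; attribute `terminator` gives the
#'   designated terminator's start and length. A trailer with no >=4-T
#'   run is an error.
#' @export
check_internal_terminator <- function(cassette) {
  full <- cassette_seq(cassette)
  t_runs <- function(s) {
    m <- gregexpr("T{4,}", s)[[1]]
    if (m[1] == -1) return(data.frame(position = integer(0),
                                      runlength = integer(0)))
    data.frame(position = as.integer(m) - 1L,
               runlength = attr(m, "match.length"))
  }
  trailer_runs <- t_runs(cassette$trailer3)
  if (!nrow(trailer_runs))
    stopf("trailer3 has no >=4-T run: cassette lacks a terminator")
  term_start <- nchar(cassette$uce5) + nchar(cassette$body) +
    trailer_runs$position[1]
  runs <- t_runs(full)
  warn <- runs[runs$position < term_start, , drop = FALSE]
  rownames(warn) <- NULL
  attr(warn, "terminator") <- c(position = term_start,
                                runlength = trailer_runs$runlength[1])
  warn
}

#' Synthetic-accessibility filter for long UCE sequences
#'
#' Default exclusion predicate for the 850-bp UCE class: rejects sequences
#' with a homopolymer run longer than 15 nt or GC content outside 20-80%
#' (a generic proxy for vendor synthesis constraints). Supply your own
#' predicate to [extract_flanks] output when a different rule is needed.
#'
#' @param seqs character vector of DNA sequences.
#' @return logical vector, `TRUE` = synthetically accessible.
#' @export
synthetically_accessible <- function(seqs) {
  vapply(seqs, function(s) {
    if (grepl("A{16,}|C{16,}|G{16,}|T{16,}", s)) return(FALSE)
    gc <- sum(strsplit(s, "")[[1]] %in% c("G", "C")) / nchar(s)
    gc >= 0.2 && gc <= 0.8
  }, logical(1), USE.NAMES = FALSE)
}

#' Manifest of a member library
#'
#' @param members list of library members.
#' @return data.frame with `member_id`, `library_class`, `original`,
#'   `n_edits`, `edits` (compact `pos:from>to` strings) and `seq`.
#' @export
library_manifest <- function(members) {
  data.frame(
    member_id = vapply(members, `[[`, character(1), "member_id"),
    library_class = vapply(members, `[[`, character(1), "library_class"),
    original = vapply(members, `[[`, logical(1), "original"),
    n_edits = vapply(members, function(m) nrow(m$edits), integer(1)),
    edits = vapply(members, function(m)
      paste(sprintf("%d:%s>%s", m$edits$position, m$edits$from, m$edits$to),
            collapse = ";"), character(1)),
    seq = vapply(members, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE)
}
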