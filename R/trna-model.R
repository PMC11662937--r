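#' tRNA gene record
#'
#' Bundles a tRNA gene's genomic identity (BED-style 0-based half-open
#' coordinates), its body sequence in transcriptional sense, and its
#' secondary structure as a dot-bracket string.
#'
#' @param gene_id unique gene identifier (GtRNAdb-style names work well,
#'   e.g. `"tRNA-Arg-TCT-3-1"`).
#' @param chrom chromosome name.
#' @param start,end 0-based half-open genomic interval of the gene body.
#' @param strand `"+"` or `"-"`.
#' @param body_seq DNA string of the tRNA body on the coding strand,
#'   5' to 3' of the tRNA (i.e. already reverse-complemented for `-` genes).
#' @param structure dot-bracket string, same length as `body_seq`.
#' @param isotype amino-acid isotype label (e.g. `"Arg"`), optional.
#' @param anticodon_dna anticodon as a DNA 3-mer, optional; when a valid
#'   cloverleaf can be built it is checked against the body sequence.
#'
#' @return An object of class `"trna_gene_record"` (a named list).
#' @export
trna_gene_record <- function(gene_id, chrom, start, end, strand, body_seq,
                             structure = NULL, isotype = NA_character_,
                             anticodon_dna = NA_character_) {
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-', got '%s'", strand)
  if (!is_dna(body_seq)) stopf("body_seq of '%s' is not plain ACGT DNA", gene_id)
  if (end - start != nchar(body_seq))
    stopf("record '%s': end-start (%d) != body length (%d)",
          gene_id, end - start, nchar(body_seq))
  if (!is.null(structure) && nchar(structure) != nchar(body_seq))
    stopf("record '%s': structure length != body length", gene_id)
  structure(
    list(gene_id = gene_id, chrom = chrom, start = as.integer(start),
         end = as.integer(end), strand = strand, body_seq = body_seq,
         structure = structure, isotype = isotype,
         anticodon_dna = anticodon_dna),
    class = "trna_gene_record"
  )
}

#' @export
print.trna_gene_record <- function(x, ...) {
  cat(sprintf("<trna_gene_record> %s  %s:%d-%d(%s)  %d nt  isotype=%s\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nchar(x$body_seq), x$isotype))
  invisible(x)
}

#' Parse tRNA genes from BED6 annotation plus a genome FASTA
#'
#' Reads gene intervals from a BED6 file, extracts each body sequence from
#' the genome (reverse-complemented for minus-strand genes so that
#' `body_seq` is always the tRNA's own 5'->3' sense), and optionally joins
#' dot-bracket structures from a two-column TSV (`gene_id`, `structure`).
#'
#' @param bed path to a BED6 file (`chrom start end name score strand`).
#' @param genome path to the genome FASTA, or a named
#'   [Biostrings::DNAStringSet].
#' @param structures optional path to a TSV with columns `gene_id` and
#'   `structure`, or a data.frame with those columns.
#' @return A list of [trna_gene_record] objects in input order.
#' @export
parse_trna_genes <- function(bed, genome, structures = NULL) {
  gr <- rtracklayer::import(bed, format = "BED")
  genome <- load_genome(genome)
  nm <- as.character(gr$name)
  if (anyDuplicated(nm))
    stopf("duplicate gene_ids in BED: %s",
          paste(unique(nm[duplicated(nm)]), collapse = ", "))
  st <- NULL
  if (!is.null(structures)) {
    st <- if (is.data.frame(structures)) structures
          else utils::read.delim(structures, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "structure") %in% names(st)))
      stopf("structures table needs columns gene_id and structure")
  }
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    chrom <- as.character(GenomicRanges::seqnames(gr[i]))
    if (!chrom %in% names(genome))
      stopf("record '%s': chromosome '%s' missing from genome", nm[i], chrom)
    s0 <- GenomicRanges::start(gr[i]) - 1L   # back to 0-based half-open
    e0 <- GenomicRanges::end(gr[i])
    if (s0 < 0L || e0 > nchar(genome[[chrom]]))
      stopf("record '%s': %s:%d-%d out of chromosome range", nm[i], chrom, s0, e0)
    strand <- as.character(GenomicRanges::strand(gr[i]))
    if (!strand %in% c("+", "-"))
      stopf("record '%s': strand must be + or -", nm[i])
    seq <- substr(genome[[chrom]], s0 + 1L, e0)
    if (strand == "-") seq <- revcomp(seq)
    struct_i <- if (!is.null(st)) {
      j <- match(nm[i], st$gene_id)
      if (is.na(j)) NULL else st$structure[j]
    }
    out[[i]] <- trna_gene_record(nm[i], chrom, s0, e0, strand, seq,
                                 structure = struct_i)
  }
  out
}

# Accept a FASTA path or a DNAStringSet; return a named character vector.
#' @noRd
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    out <- as.character(genome)
    # FASTA headers may carry descriptions after whitespace
    names(out) <- sub("\\s.*$", "", names(genome))
    return(out)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stopf("genome must be a FASTA path, DNAStringSet, or named character vector")
}

# Stack-based dot-bracket matcher: returns a 2-column matrix of 0-based
# (i, j) pairs, i < j, ordered by i.
#' @noRd
match_brackets <- function(db) {
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c("(", ")", "."))) stopf("structure has characters outside (.)")
  stack <- integer(0)
  pairs <- matrix(integer(0), ncol = 2)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stopf("unbalanced dot-bracket (unmatched ')')")
      pairs <- rbind(pairs, c(stack[length(stack)], i))
      stack <- stack[-length(stack)]
    }
  }
  if (length(stack)) stopf("unbalanced dot-bracket (unmatched '(')")
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  pairs - 1L
}

# Group base pairs into helices: consecutive stacked pairs
# (i+1, j-1) directly inside (i, j) belong to one helix.
#' @noRd
group_helices <- function(pairs) {
  if (!nrow(pairs)) return(list())
  helices <- list()
  cur <- pairs[1, , drop = FALSE]
  for (r in seq_len(nrow(pairs))[-1]) {
    prev <- cur[nrow(cur), ]
    if (pairs[r, 1] == prev[1] + 1L && pairs[r, 2] == prev[2] - 1L) {
      cur <- rbind(cur, pairs[r, ])
    } else {
      helices[[length(helices) + 1L]] <- cur
      cur <- pairs[r, , drop = FALSE]
    }
  }
  helices[[length(helices) + 1L]] <- cur
  helices
}

#' Build a cloverleaf model from a tRNA gene record
#'
#' Parses the record's dot-bracket structure into the four canonical tRNA
#' helices (acceptor, D, anticodon, T stems in 5'->3' order), the loops,
#' and the functional index sets the cassette libraries target: the
#' anticodon triplet (Sprinzl 34-36), its loop flanks (Sprinzl 32, 33, 37,
#' 38) and the three outermost t-stem pairs (Sprinzl 49-65, 50-64, 51-63).
#' All indices are 0-based into `body_seq`; Sprinzl numbers are labels
#' assigned by helix order, not by alignment to a reference tRNA.
#'
#' G.T wobble pairs in stems are accepted and reported in `$wobble_pairs`;
#' any other non-complementary pair is an error.
#'
#' @param rec a [trna_gene_record] with a non-NULL `structure`, or a list
#'   with elements `body_seq` and `structure`.
#' @return An object of class `"cloverleaf"`: a list with elements
#'   `acceptor_stem`, `d_stem`, `ac_stem`, `t_stem` (2-column 0-based index
#'   matrices, outermost pair first), `loops` (named list of index
#'   vectors: the four loops `d_loop`, `ac_loop`, `variable`, `t_loop`,
#'   the inter-stem linkers, and the `trailing` 3' discriminator/NCCA-style
#'   overhang; together with the stems these partition the body),
#'   `anticodon`, `ac_loop_flank`, `tstem_pairs_49_51`, `wobble_pairs`,
#'   and `length`.
#' @export
build_cloverleaf <- function(rec) {
  body <- rec$body_seq
  db <- rec$structure
  if (is.null(db)) stopf("record has no dot-bracket structure")
  if (nchar(db) != nchar(body)) stopf("structure length != body length")
  pairs <- match_brackets(db)
  helices <- group_helices(pairs)
  if (length(helices) != 4L)
    stopf("expected 4 helices (acceptor, D, anticodon, T), found %d",
          length(helices))
  # Acceptor stem must enclose the other three
  acc <- helices[[1]]
  inner <- helices[2:4]
  encl <- vapply(inner, function(h)
    all(h[, 1] > max(acc[, 1]) & h[, 2] < min(acc[, 2])), logical(1))
  if (!all(encl))
    stopf("first helix does not enclose the other three; not a cloverleaf")
  d_stem <- inner[[1]]; ac_stem <- inner[[2]]; t_stem <- inner[[3]]

  loop_of <- function(stem) {
    (max(stem[, 1]) + 1L):(min(stem[, 2]) - 1L)
  }
  ac_loop <- loop_of(ac_stem)
  if (length(ac_loop) != 7L)
    stopf("anticodon loop has %d positions, expected 7", length(ac_loop))
  d_loop <- loop_of(d_stem)
  t_loop <- loop_of(t_stem)
  variable <- integer(0)
  if (min(t_stem[, 1]) > max(ac_stem[, 2]) + 1L)
    variable <- (max(ac_stem[, 2]) + 1L):(min(t_stem[, 1]) - 1L)
  trailing <- integer(0)  # discriminator / NCCA-style 3' overhang
  if (max(acc[, 2]) < nchar(body) - 1L)
    trailing <- (max(acc[, 2]) + 1L):(nchar(body) - 1L)
  # linkers between consecutive stems, so stems + loops partition the body
  span_between <- function(a, b) if (b > a + 1L) (a + 1L):(b - 1L)
                                 else integer(0)
  acc_d_linker <- span_between(max(acc[, 1]), min(d_stem[, 1]))
  d_ac_linker <- span_between(max(d_stem[, 2]), min(ac_stem[, 1]))
  t_acc_linker <- span_between(max(t_stem[, 2]), min(acc[, 2]))

  # check complementarity, flagging G.T wobbles
  b <- strsplit(body, "")[[1]]
  wob <- matrix(integer(0), ncol = 2)
  for (h in helices) for (r in seq_len(nrow(h))) {
    x <- b[h[r, 1] + 1L]; y <- b[h[r, 2] + 1L]
    if (comp_base(x) == y) next
    if (paste0(x, y) %in% c("GT", "TG")) wob <- rbind(wob, h[r, ])
    else stopf("non-complementary stem pair %s-%s at (%d,%d)",
               x, y, h[r, 1], h[r, 2])
  }

  anticodon <- ac_loop[3:5]
  cl <- structure(
    list(acceptor_stem = acc, d_stem = d_stem, ac_stem = ac_stem,
         t_stem = t_stem,
         loops = list(acc_d_linker = acc_d_linker, d_loop = d_loop,
                      d_ac_linker = d_ac_linker, ac_loop = ac_loop,
                      variable = variable, t_loop = t_loop,
                      t_acc_linker = t_acc_linker, trailing = trailing),
         anticodon = anticodon,
         ac_loop_flank = ac_loop[c(1, 2, 6, 7)],
         tstem_pairs_49_51 = t_stem[seq_len(min(3L, nrow(t_stem))), ,
                                    drop = FALSE],
         wobble_pairs = wob,
         length = nchar(body)),
    class = "cloverleaf"
  )
  # cross-check a declared anticodon, if the record carries one
  if (inherits(rec, "trna_gene_record") && !is.na(rec$anticodon_dna)) {
    got <- paste(b[anticodon + 1L], collapse = "")
    if (got != rec$anticodon_dna)
      stopf("declared anticodon %s != structural anticodon %s",
            rec$anticodon_dna, got)
  }
  cl
}

#' @export
print.cloverleaf <- function(x, ...) {
  cat(sprintf(paste0("<cloverleaf> %d nt; stems (bp): acceptor %d, D %d, ",
                     "anticodon %d, T %d; anticodon at %s%s\n"),
              x$length, nrow(x$acceptor_stem), nrow(x$d_stem),
              nrow(x$ac_stem), nrow(x$t_stem),
              paste(x$anticodon, collapse = ","),
              if (nrow(x$wobble_pairs)) sprintf("; %d wobble pair(s)",
                                                nrow(x$wobble_pairs)) else ""))
  invisible(x)
}

#' All base-paired positions of a cloverleaf
#'
#' @param cl a [build_cloverleaf] result.
#' @return 2-column 0-based index matrix of every stem pair, ordered by the
#'   5' index.
#' @export
cloverleaf_pairs <- function(cl) {
  p <- rbind(cl$acceptor_stem, cl$d_stem, cl$ac_stem, cl$t_stem)
  p[order(p[, 1]), , drop = FALSE]
}
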