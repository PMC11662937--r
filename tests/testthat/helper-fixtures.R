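# Shared fixtures and independent oracles. Oracles deliberately use
# different algorithms from the package implementation.

CANON_DB <- paste0(
  "(((((((", "..",
  "((((", "........", "))))", ".",
  "(((((", ".......", ")))))",
  ".....",
  "(((((", ".......", ")))))",
  ")))))))", "....")

# Build a body for a dot-bracket by specifying the 5' base of every pair
# (in 5'-index order) and filling unpaired positions from a repeating
# pattern. Complementary 3' strands, no wobbles.
body_from_structure <- function(db, pair5, loop_fill = "ACGT") {
  pr <- oracle_pairs(db)
  stopifnot(length(pair5) == nrow(pr))
  ch <- strsplit(db, "")[[1]]
  b <- character(length(ch))
  unp <- which(ch == ".")
  fill <- strsplit(loop_fill, "")[[1]]
  b[unp] <- rep_len(fill, length(unp))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  b[pr[, 1] + 1] <- pair5
  b[pr[, 2] + 1] <- comp[pair5]
  paste(b, collapse = "")
}

# Independent bracket matcher: for each '(', walk forward counting depth.
oracle_pairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  opens <- which(ch == "(")
  out <- matrix(NA_integer_, length(opens), 2)
  for (k in seq_along(opens)) {
    depth <- 0
    for (j in opens[k]:length(ch)) {
      if (ch[j] == "(") depth <- depth + 1
      if (ch[j] == ")") depth <- depth - 1
      if (depth == 0) { out[k, ] <- c(opens[k], j); break }
    }
  }
  out <- out[order(out[, 1]), , drop = FALSE]
  out - 1L
}

# A deterministic canonical 76-nt tRNA record (21 pairs).
canon_record <- function(pair5 = NULL) {
  if (is.null(pair5))
    pair5 <- strsplit("GCGGATTAGCTCAGTGGTAGA", "")[[1]][1:21]
  body <- body_from_structure(CANON_DB, pair5)
  trna_gene_record("canon-1", "chrN", 0L, nchar(body), "+", body,
                   structure = CANON_DB)
}

# Target + one family member carrying C-G at n_sites chosen A/T pairs.
sticky_fixture <- function(n_sites) {
  pair5 <- rep(c("A", "G"), length.out = 21)   # A-T pairs at odd slots
  at <- which(pair5 == "A")
  stopifnot(n_sites <= length(at))
  body_t <- body_from_structure(CANON_DB, pair5)
  fam5 <- pair5
  fam5[at[seq_len(n_sites)]] <- "C"
  body_f <- body_from_structure(CANON_DB, fam5)
  cl_t <- build_cloverleaf(list(body_seq = body_t, structure = CANON_DB))
  cl_f <- build_cloverleaf(list(body_seq = body_f, structure = CANON_DB))
  list(target = list(body = body_t, cl = cl_t),
       family = list(list(body = body_f, cl = cl_f)),
       sites = at[seq_len(n_sites)])
}

# Brute-force tryptic peptide enumeration: all substrings whose ends are
# valid cleavage boundaries and whose internal missed-cleavage count is
# within the cap.
oracle_digest <- function(protein, max_missed = 2) {
  aa <- strsplit(protein, "")[[1]]
  n <- length(aa)
  is_cut <- function(i) i >= 1 && i < n && aa[i] %in% c("K", "R") &&
    aa[i + 1] != "P"
  res <- character(0)
  for (i in 1:n) for (j in i:n) {
    ok_start <- i == 1 || is_cut(i - 1)
    ok_end <- j == n || is_cut(j)
    if (!ok_start || !ok_end) next
    internal <- if (j > i) sum(vapply((i):(j - 1), is_cut, logical(1)))
                else 0
    if (internal <= max_missed)
      res <- c(res, paste(aa[i:j], collapse = ""))
  }
  res
}

# Exact two-sided binomial P by direct log-space summation (independent
# of dbinom-based implementation path).
oracle_binom_p <- function(k, n, p0) {
  lp <- lchoose(n, 0:n) + (0:n) * log(p0) + (n - (0:n)) * log1p(-p0)
  pk <- lp[k + 1]
  min(1, sum(exp(lp[lp <= pk + 1e-12])))
}

random_protein <- function(n) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                 "Q","R","S","T","V","W","Y"), n, replace = TRUE),
        collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
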