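test_that("tryptic digest: hand cases and the KP suppression rule", {
  expect_equal(tryptic_digest("MKAGRSTP", 0)$sequence,
               c("MK", "AGR", "STP"))
  expect_equal(tryptic_digest("AKPR", 0)$sequence, "AKPR")
  d2 <- tryptic_digest("MKAGRSTP", 2)
  expect_setequal(d2$sequence,
                  c("MK", "MKAGR", "MKAGRSTP", "AGR", "AGRSTP", "STP"))
  expect_equal(d2$missed[d2$sequence == "MKAGRSTP"], 2)
  expect_error(tryptic_digest("AXZ"), "invalid residue")
})

test_that("digest equals brute-force enumeration on fuzzed 50-mers", {
  set.seed(55)
  for (i in 1:40) {
    p <- random_protein(50)
    got <- tryptic_digest(p, 2)$sequence
    expect_setequal(got, oracle_digest(p, 2))
  }
})

test_that("peptide masses are additive and match a residue-table oracle", {
  masses <- c(G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276,
              V = 99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
              I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
              K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
              F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
  set.seed(56)
  for (i in 1:20) {
    pep <- random_protein(sample(5:25, 1))
    aa <- strsplit(pep, "")[[1]]
    want <- sum(masses[aa]) + 18.0105646863 + sum(aa == "C") * 57.02146
    expect_equal(peptide_mass(pep), want, tolerance = 1e-4)
  }
  # m/z columns back-compute the neutral mass at every charge
  d <- tryptic_digest("ACDEFK", 0)
  for (z in 2:5)
    expect_equal(d[[paste0("mz_", z)]],
                 (d$mono_mass + z * 1.00727646688) / z, tolerance = 1e-9)
})

test_that("variant inclusion list: 20 distinct site-spanning peptides", {
  prot <- paste0("MA", strrep("G", 5), "K", "AGTCAS", "R",
                 "VLTESTX", "R", "MGGK")
  prot <- gsub("X", "N", prot)
  site <- 18   # inside the third tryptic fragment
  il <- variant_inclusion_list(prot, site)
  expect_equal(nrow(il), 20)
  expect_false(anyDuplicated(il$sequence) > 0)
  expect_setequal(il$variant_aa,
                  c("A","C","D","E","F","G","H","I","K","L",
                    "M","N","P","Q","R","S","T","V","W","Y"))
  expect_true(all(il$start <= site & il$end >= site))
  # K/R substitution at the site forces a missed cleavage
  expect_gte(il$missed[il$variant_aa == "K"], 1)
  expect_gte(il$missed[il$variant_aa == "R"], 1)
  # non-K/R variants span with the minimal (0) missed cleavage here
  expect_equal(il$missed[il$variant_aa == "G"], 0)
  # masses: substituting the site residue shifts mass by the residue diff
  base <- il[il$variant_aa == "G", ]
  va <- il[il$variant_aa == "A", ]
  expect_equal(va$mono_mass - base$mono_mass, 71.03711 - 57.02146,
               tolerance = 1e-4)
})

test_that("oxidized-methionine entries expand the m/z table", {
  prot <- paste0("MAMGK", "TESTR", "GGK")
  il <- variant_inclusion_list(prot, 3)
  mz <- inclusion_mz_table(il)
  m_row <- il[il$variant_aa == "M", ]
  # the all-M peptide has n_met M's, so n_met+1 oxidation states x 4 charges
  expect_equal(sum(mz$sequence == m_row$sequence),
               (m_row$n_met + 1) * 4)
  # one oxidation adds 15.99491 to the neutral mass at every charge
  sub <- mz[mz$sequence == m_row$sequence & mz$z == 2, ]
  expect_equal(diff(sort(sub$mz)) * 2, rep(15.99491, nrow(sub) - 1),
               tolerance = 1e-5)
})

test_that("ionization weights make the equimolar control uniform", {
  expect_equal(ionization_weights(c(A = 5, R = 5, K = 5)),
               c(A = 1, R = 1, K = 1))
  w <- ionization_weights(c(A = 2, R = 1))
  expect_equal(w, c(A = 0.75, R = 1.5))
  expect_equal(unname(2 * w["A"]), unname(1 * w["R"]))  # reweighted uniform
  expect_warning(w2 <- ionization_weights(c(A = 1, R = 0)), "excluding")
  expect_named(w2, "A")
  # noiseless synthetic: weights recover reciprocal ionization factors
  cfg <- sim_config(seed = 8, ms_cv = 0)
  ms <- sim_ms(cfg)
  w3 <- ionization_weights(ms$control)
  fac <- cfg$ionization[names(w3)]
  v <- unname(w3 * fac)            # w ~ 1/factor up to a common scale
  expect_equal(v / v[1], rep(1, length(v)), tolerance = 1e-12)
})

test_that("percent incorporation recovers truth despite ionization distortion", {
  # single detected amino acid
  w <- ionization_weights(c(R = 1, K = 1))
  t1 <- percent_incorporation(c(R = 123, K = 0), w)
  expect_equal(t1$percent[t1$aa == "R"], 100)
  # uniform weights = plain normalization
  s <- c(R = 80, K = 15, W = 5)
  t2 <- percent_incorporation(s, c(R = 1, K = 1, W = 1))
  expect_equal(t2$percent, unname(100 * sort(s, decreasing = TRUE) / sum(s)))
  # generative recovery, truth 99.9% cognate, noiseless, arbitrary factors
  cfg <- sim_config(seed = 9, ms_cv = 0,
                    incorporation = c(R = 0.999, K = 0.0005, W = 0.0005),
                    ionization = c(R = 0.2, K = 9, W = 3))
  ms <- sim_ms(cfg)
  tab <- percent_incorporation(ms$sample, ionization_weights(ms$control))
  expect_equal(tab$percent[tab$aa == "R"], 99.9, tolerance = 1e-9)
  # invariance: scaling one amino acid's true ionization efficiency
  for (c_ in c(0.1, 7)) {
    cfg2 <- sim_config(seed = 9, ms_cv = 0,
                       incorporation = c(R = 0.999, K = 0.0005, W = 0.0005),
                       ionization = c(R = 0.2, K = 9 * c_, W = 3))
    ms2 <- sim_ms(cfg2)
    tab2 <- percent_incorporation(ms2$sample, ionization_weights(ms2$control))
    expect_equal(tab2$percent, tab$percent, tolerance = 1e-9)
  }
  expect_error(percent_incorporation(c(R = 0, K = 0), w), "zero")
})
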