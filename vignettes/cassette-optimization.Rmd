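---
title: "Methods: suppressor-tRNA cassette optimization with acetrnaopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suppressor-tRNA cassette optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acetrnaopt)
```

## Scope

`acetrnaopt` covers the computational core of an ACE-tRNA
(anticodon-edited suppressor tRNA) cassette optimization campaign: the
structural model of the tRNA gene, the design of every cassette library
class, the scoring of dual-luciferase suppression screens, motif
inference from activity-weighted libraries, DNA dose-response
characterization, translational-fidelity quantification from targeted
proteomics, and comparative-Ct transcript quantification. Wet-lab steps
(cloning, transfection, purification, the MS database search itself) are
out of scope; the package consumes or emulates their outputs.

## The cloverleaf model

A tRNA gene record carries 0-based half-open genomic coordinates
(BED convention), the body sequence in the tRNA's own 5'→3' sense
(minus-strand genes are reverse-complemented on extraction), and a
dot-bracket secondary structure. `build_cloverleaf()` requires a balanced
dot-bracket with exactly four helices in cloverleaf order — acceptor, D,
anticodon, T — where the first helix encloses the other three. Stems are
recovered by stack-based bracket matching and grouped into helices of
directly stacked pairs; the anticodon is the central three nucleotides of
the mandatory 7-nt anticodon loop. Sprinzl-style labels (anticodon 34–36,
loop flanks 32/33/37/38, t-stem pairs 49–65/50–64/51–63) are assigned by
helix order, not by alignment to a reference tRNA: the libraries only
need stable names for those positions, and helix order provides them for
any cloverleaf-shaped input. Structures are required input (annotation
databases and the synthetic generator both provide them); no folding
algorithm is implemented, because the design procedure never folds tRNAs.
G·T wobble pairs in stems are accepted and flagged rather than rejected —
they are common in natural tRNAs. Stems, loops, inter-stem linkers and
the 3' trailing (discriminator/NCCA-like) region partition every body
index exactly once.

## Library classes

*Flank libraries.* `extract_flanks()` takes the 5' UCE (default 55 bp, or
850 bp for the long class) or 3' trailer (35 bp) of every gene in
transcriptional sense and collapses exact duplicates, keeping the first
occurrence's gene as provenance — "unique" is exact string identity, no
clustering. Genes whose flank would leave the chromosome are skipped with
a warning rather than failing the batch. For the 850-bp class,
`synthetically_accessible()` supplies a default vendor-style exclusion
rule (homopolymer runs > 15 nt or GC outside 20–80%); the real vendor
criterion is proprietary, so the predicate is user-replaceable.

*Saturation libraries.* `enumerate_saturation()` yields all 4^k
assignments of A/C/G/T to k template positions, ordered lexicographically
by the substituted k-mer so that heat-map layouts are reproducible (the
screen's column order carries no meaning; a deterministic order makes
reruns comparable). k = 4 gives the 256-member trailer and anticodon-loop
classes.

*Sticky stems.* `design_sticky_stem_library()` stabilizes stems by
C–G/G–C substitution at positions where a functional isoacceptor family
member already carries such a pair. A stem pair qualifies when it is not
conserved across target plus family and at least one family member holds
C–G or G–C there; the introduced pair is that member's, taking the first
member in input order on ties (the tie rule is otherwise unspecified in
the field's practice, and first-in-order is deterministic and auditable).
All 2^k combinations over the k sites are emitted, both strands of a pair
substituted jointly, member ids encoding the site bitmask.

*t-stems.* `design_tstem_library()` swaps the three outermost t-stem
pairs (optionally five) to each row of a variant table — the panel
spanning a range of elongation-factor affinities is supplied as data, not
hard-coded, since it originates from external thermodynamic
measurements. Non-complementary specified pairs are errors; G–T wobbles
are allowed and flagged.

*Oligos and terminators.* `make_golden_gate_oligos()` produces the
annealed duplex with two distinct 4-nt 5' overhangs and
`assemble_golden_gate()` verifies the ligation product in silico;
identical or reverse-complementary overhangs are rejected because they
ligate in either orientation. `check_internal_terminator()` reports every
≥4-T run on the coding strand upstream of the trailer's designated
terminator — RNA polymerase III terminates at four or more thymidines, so
an internal run truncates the transcript — and treats a trailer without
any ≥4-T run as a hard design error.

## Screen scoring

The screen statistic is the normalized suppression ratio
\[(N^+/F^+) / (N^-/F^-)\]
with N the PTC-reporter NanoLuc signal, F the firefly transfection
control, and the minus terms from no-tRNA control wells. Any multiplier
that hits both channels of a well — transfection efficiency above all —
cancels exactly, which is the property that makes the screen robust; the
package verifies it as an invariant (lognormal per-well efficiency with
σ up to 1 changes no ratio beyond floating point).

Per plate, member wells are normalized to the *geometric* mean of that
plate's control wells' N/F: ratios are multiplicative, so the geometric
mean is the natural center (the control aggregation rule is otherwise a
free choice). The control itself is summarized from its per-plate
aggregate, so its mean is exactly 1 by construction. Whether the no-tRNA
denominator should be per-plate or per-experiment is genuinely open;
per-plate is the default because it absorbs plate-to-plate scale drift.
Replicate summaries use the sample standard deviation (n−1) for the SEM.
No background subtraction is applied. Fold changes are reported against a
reference cassette (`reference_normalize()`), and `heatmap_matrix()`
arranges members row-major with explicit NA padding.

## Activity-weighted logos

Library screens are converted to motif information by treating each
member's suppression ratio as its sequence abundance: a ratio of 100
counts as 100 copies of that sequence. `weight_to_counts()` rounds means
to integer copies with R's round-half-to-even and floors at zero; members
rounding to zero are retained with count 0 (no activity filter is applied
before weighting — keeping weak members is the conservative default, and
a caller can subset first). Every weighted computation is identical to
the unweighted computation on the count-expanded set, and the tests
enforce that equivalence.

Significance logos use an exact two-sided binomial test per position and
base: k = weighted count of the base, n = total weight, p0 = background
frequency, with the two-sided P defined as the sum of all outcome
probabilities not exceeding the observed one. The statistic is signed
−log10 P (positive enriched, negative depleted, 0 when the observed
frequency equals background exactly) and capped at 300 to keep the matrix
finite. The default background pools base frequencies over all positions
of the weighted set; uniform or user-supplied backgrounds are options.
Only single positions are modelled (k-mer motifs are out of scope).
Consensus sequences take the per-position argmax (high) or argmin (low)
of either matrix, ties broken alphabetically.

## Dose-response model

Suppression as a function of delivered DNA dose D (ng/µl) is fit as

S(D) = 1 + (Sup_max − 1) · D / (DD50 + D)

a rectangular hyperbola with the baseline fixed at 1 — forced by the
ratio definition, since no tRNA means a ratio of 1 — and a unit Hill
exponent. The exponent is exposed (`hill`) for sensitivity analysis, but
1 is the declared default in the absence of evidence for cooperativity in
DNA delivery. S(DD50) = (1 + Sup_max)/2, half-maximal above baseline.
Fitting is unweighted least squares on the ratio scale
(`minpack.lm::nlsLM`, bounds Sup_max ≥ 1, DD50 > 0), initialized at
Sup_max = max ratio and DD50 = the dose nearest half-max; flat data fit
Sup_max ≈ 1 with DD50 flagged unidentifiable rather than erroring.
Bootstrap CIs resample replicate series with a recorded seed. The
`dose_fit` object supports `print`, `summary`, `coef`, `predict`,
`residuals`, `plot` and `simulate`.

Dose sparing between cassettes inverts the model analytically,
D(level) = DD50 · (level − 1)/(Sup_max − level), and reports
D_original/D_optimized at a shared suppression level; at the common
midpoint of two fits with equal Sup_max this is exactly the DD50 ratio.

## Translational fidelity

`tryptic_digest()` cleaves C-terminal to K/R except before P (the
classical trypsin rule; search engines differ on the KP exception, so it
is the documented default) and enumerates peptides with up to two missed
cleavages. `variant_inclusion_list()` builds the targeted-MS inclusion
list for a substitution site: for each of the 20 amino acids, the
minimal-missed-cleavage peptide spanning the site *with at least one
residue of context on each side*. The context requirement makes the
variant positionally unambiguous and has one important consequence: a K
or R substitution creates a new cleavage site at the variant position, so
its spanning peptide necessarily carries a missed cleavage. One peptide
per variant gives exactly 20 distinct sequences.
Carbamidomethyl-cysteine is a fixed modification (+57.02146 Da);
methionine oxidation (+15.99491 Da) expands the m/z table
(`inclusion_mz_table()`, charges 2–5, monoisotopic masses from the
standard residue table plus water).

Peptides ionize unequally, so raw abundances are corrected with weights
from an equimolar control mix: weight = mean(control)/control, making the
reweighted control uniform by construction. Percent incorporation is the
weighted sample abundance over its total, ×100. The correction is exactly
invariant to rescaling any amino acid's true ionization efficiency, which
is its purpose. Database search, FDR control and feature detection happen
upstream; the module consumes their per-amino-acid abundance output.

## Comparative Ct

`relative_quantity()` implements textbook 2^−ΔΔCt with amplification
efficiency fixed at 2: ΔCt = mean target Ct − mean reference Ct per
sample, ΔΔCt against a single calibrator, RQ = 2^−ΔΔCt (calibrator ≡ 1).
Technical-replicate outliers are not removed by default — no principled
rule is available without melt-curve context — and efficiency-corrected
variants are out of scope.

## The synthetic-data generators

Every simulator is a seeded pure function of a `sim_config` (the global
RNG stream is saved and restored), and each embeds its ground truth for
recovery tests. Defaults are the study conditions: 55-bp UCEs, 35-bp
trailers, six independent transfections per member, 10% lognormal channel
noise with per-well lognormal transfection efficiency (σ 0.5; the
efficiency multiplies both channels and must cancel), an 8-dose 2-fold
dilution series (0.39–50 ng/µl) around DD50 = 8 ng/µl with Sup_max = 40
and 10% CV, 98% cognate incorporation against distorting ionization
factors, Gaussian Ct noise of 0.1 cycles, and 30 planted genes of which
3 share a 5' flank (so deduplication has a known answer). Where the
underlying campaign did not state a value (luminescence base levels, Ct
baselines, chromosome padding), values were chosen once at realistic
orders of magnitude and left alone.

What the generators do *not* emulate: plate edge effects, luminescence
background and crosstalk, saturating detector response, sequence-
dependent synthesis failures, chromatographic missingness in MS, or
amplification-efficiency drift in qPCR. Passing recovery tests therefore
demonstrates correctness of the estimators under their own generative
assumptions, not robustness to every artifact of real instruments.

## Numerical choices and problem sizes

Exact binomial P values are computed by direct summation of dbinom terms
(capped at −log10 P = 300); equality of observed and background frequency
short-circuits to 0. Copy counts round half to even. Dose fits use
Levenberg–Marquardt with tight tolerances (ftol/ptol 1e-12, 500
iterations). The test suite runs the property checks at sizes that keep
the whole suite around half a minute: ~10^4 simulated wells for the
ratio-invariance property, 100 fuzzed sets for logo equivalence, 50 seeds
for dose-response recovery, 200 fuzzed 50-mers for the digest oracle;
these sizes were chosen as comfortably sufficient for the properties
being demonstrated.

## Interface notes

The package's interface is its exported functions plus
`scripts/acceptance.R`; analyses in this domain are driven from R, so no
standalone command-line tool is shipped. The classic modelling idiom is
reserved for the one genuine estimator (`fit_dose_response()`), which
returns a classed S3 object with the full complement of methods.

## Known limitations

Sprinzl labels are positional conveniences and will mislabel deeply
non-canonical tRNAs (e.g. type II variable arms are treated as a generic
variable loop). The sticky-stem tie rule and the per-plate control choice
are defensible defaults, not uniquely correct ones; both are exposed.
The dose model's unit Hill exponent and fixed baseline are assumptions —
the `hill` argument exists precisely so their impact can be checked. The
20-peptide inclusion list treats K/R variants' extra cleavage products as
alternative charge/oxidation entries of one representative peptide, not
as additional list members.
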