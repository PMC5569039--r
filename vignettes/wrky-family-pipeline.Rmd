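---
title: "Methods: WRKY family identification, promoter survey and expression calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: WRKY family identification, promoter survey and expression calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wrkyscan)
```

# The problem

Genome-wide surveys of the WRKY transcription-factor family follow a
well-worn protocol: find every protein carrying a WRKY domain, type its
zinc finger, classify members into groups I/IIa–e/III (plus a non-group for
outliers), build a bootstrapped Neighbor-Joining tree, scan 1-kb upstream
regulatory regions for the W-box and other stress-related cis-elements,
call genes with clustered W-boxes as potential WRKY targets, and test
family members for differential expression under stress. `wrkyscan` turns
that protocol into a single tested pipeline whose every stage can be
validated offline against synthetic data with recorded ground truth.

# Domain model

A WRKY domain is detected as a heptapeptide hit plus a validating zinc
finger.

**Heptapeptide.** Every 7-residue window with W, K, Y fixed at positions
1, 3, 4 and Hamming distance ≤ `max_mismatches` (default 3) to `WRKYGQK`
is reported. The anchor/tolerance choice admits every variant observed in
published family tables (`WRKYGKK`, `WRKYGEK`, `WRKYGRD`, `WRKYATN`,
`WKKYGQK`, `WNKYGQK`, `WTKYGQK`) and nothing looser. `X` never matches any
literal — a conservative reading of ambiguous residues. Overlapping
windows are each reported.

**Zinc finger.** The first match of `C X{a} C X{b} H X [HCY]` at or after
a given index, with `a` in `[3, 7]` and `b` in `[5, 27]`. These bounds are
the envelope of all spacings printed in family tables, including the
anomalous compact `C-X3-C-X5-HXC` finger some group-III members carry;
they are configuration, not code. Ties are broken by smallest start, then
smallest spacers — deterministic and biased toward compact fingers. The
terminal coordinating residue names the finger type: CCHH, CCHC or CCHY.

**Assembly.** A heptapeptide pairs with the first finger starting within
`linker_max` (default 120) residues after it; hits without a finger are
dropped. This is the family definition's own filter: a variant
heptapeptide counts only when a finger confirms it. Proteins with exactly
two assembled domains have them labelled N and C.

# Classification

Structural rules decide what they can: two domains → group I; a single
CCHC domain → group III. A single CCHH/CCHY domain cannot be placed by
structure alone — subgroups IIa–IIe and the non-group can share identical
finger grammars (e.g. `C-X4-C-X23-HXH` occurs in both IIc and NG members)
— so the domain region (heptapeptide start through finger end) is globally
aligned to a subgroup-labelled reference panel, and the best fractional
identity decides: at or above `identity_floor` (default 0.35) the panel
label wins (an I-labelled best hit yields the single-domain group-I case);
below it the protein is NG. Panel ties break by lexicographic reference
id, making the call order-invariant.

The packaged panel is **synthetic**: published surveys classify against a
curated set of Arabidopsis WRKY references that is not redistributable
here, so the default panel is built from per-subgroup domain templates
(correct spacing grammar per subgroup, distinct fixed content, a 20-residue
C-terminal flank that keeps chance identities of unrelated domains well
below the floor). It demonstrates and tests the mechanism; real analyses
should substitute curated domain sequences via `read_reference_panel()`.
Consequently the package does not promise to reproduce any published
group split de novo; family-level tallies are checked against the packaged
transcription of the published gene table instead.

# Alignment and trees

`align_pair()`/`build_msa()` use one affine-gap (Gotoh) profile aligner:
BLOSUM62 (shipped as a plain-text data file), gap open 10, extend 1 — a
gap of length L costs `open + (L−1)·extend`. Profile columns are scored by
expected substitution score under per-column residue frequencies; the MSA
is progressive along a UPGMA guide tree of pairwise identity distances.
The aligner is exercised against exhaustive alignment enumeration on tiny
instances in the test suite. It is pure R and meant for domain-scale
sequences, not chromosomes.

Tree distances are p-distances over alignment columns (double-gap columns
excluded, gap-vs-residue counts as mismatch) — simple, standard, and exact
to test. `nj_tree()` implements Saitou–Nei agglomeration with the Q
criterion; ties break to the lexicographically smallest active pair and
negative branch lengths clamp to zero with a notice, so output is fully
deterministic. On additive matrices the generating tree is recovered
exactly (tested to 1e-9 against independent path-length computation).
`bootstrap_support()` resamples alignment columns with replacement
(default 1000 replicates, seeded), rebuilds the NJ tree per replicate and
reports per-edge bipartition frequencies as percentages.

# Promoters and motif scanning

The promoter proxy is the ≤1000-nt window immediately 5′ of the
translation start: for a plus-strand gene, `contig[max(0, s−1000) .. s)`
with `s` the 0-based CDS start; for a minus-strand gene, the reverse
complement of the window downstream (in genome coordinates) of the CDS
end. Windows shorter than 1 kb (contig edge) are scanned as-is and
flagged truncated, not discarded. Coordinates are 0-based half-open
internally; GFF3's 1-based closed intervals convert at the reader.

Motif matches are reported on both strands (the reverse-strand scan
matches the pattern's reverse complement against the forward sequence).
The **offset convention** — published tables print positions like "−106"
without defining them — is: the offset of the match's leftmost base in
gene orientation, with −1 the base immediately before the A of ATG. This
matches "upstream of the ATG" phrasing, satisfies `offset + len ≤ 0`, and
makes the printed position sets replayable. Overlapping matches all
count; the W-box `YTGACY` is not self-reverse-complementary, so no
plus/minus double counting arises (palindromic catalog entries would be
counted once per strand, by the same rule). Offsets are emitted sorted
ascending; printed tables list them unordered, so comparisons are as sets.

Target calling: a gene with ≥3 W-boxes in its promoter is a potential
WRKY target (tiers ≥1/≥2/≥3 are all reported). The ≥3 threshold follows
the yeast-one-hybrid-motivated rule used in published surveys.

# Expression calling

**qPCR.** Per replicate, ΔCt = Ct_target − Ct_reference within the same
condition and replicate (an internal control such as actin); ΔΔCt
subtracts the mean control ΔCt; rq = 2^−ΔΔCt. The per-condition rq is the
mean of replicate-level rq values; a geometric option (2^−mean ΔΔCt, under
which the control rq is exactly 1) is available. Each condition is tested
against the control with Dunnett's many-to-one procedure: pooled
within-group variance, correlation ρij = λiλj with λi = √(ni/(ni+n0)),
and two-sided p-values from the multivariate-t null estimated by seeded
Monte Carlo (default 200,000 draws; one max|T| sample serves all
contrasts; accuracy about ±0.003, tested to ±0.005 against the closed-form
single-contrast t oracle). Whether an omnibus ANOVA should gate the
Dunnett calls is unstated in the protocol; the default gates on Dunnett
only, with an optional `omnibus_gate`. Calls: up if rq > 1.5 and
p < 0.05; down if rq ≤ 0.66 and p < 0.05 — the strict/non-strict mix
exactly as the protocol states it.

**RNA-seq.** FPKM = count·1e9 / (length · sample total). A gene is valid
when mean FPKM > 10 in either arm; fold change = mean(treated)/
mean(control) (+Inf sentinel when the control mean is zero). "Deviation
probability" is undefined in the source protocol; it is implemented here
as a seeded bootstrap direction-consistency probability — resample
replicates with replacement in both arms and report the fraction of
resamples whose fold change stays beyond the relevant threshold. This is
a documented, replaceable definition; it is not claimed to replicate any
published leaf RNA-seq call set. Up: fc ≥ 1.5 and probability ≥ 0.8;
down: fc ≤ 0.66 and probability ≥ 0.8.

# The synthetic world

Generators produce every input the pipeline consumes, with ground truth
sufficient to predict outputs exactly (domains, scans) or to stated
tolerance (expression).

- **Proteomes** (`gen_proteome`): backgrounds use alphabet restriction (no
  W/C/H/Y) so heptapeptide and finger anchors exist only where planted;
  group templates follow the family grammar (I: two blocks with X4/X22 and
  X4/X23 spacing; III: CCHC; II*: copies of panel entries; NG: variant
  heptapeptides with divergent linkers). Point mutations avoid the planted
  heptapeptide and the four finger-coordinating positions and never
  introduce W/C/H/Y, so planting recovery is exact at any rate ≤ 0.5.
- **Genomes** (`gen_genome`): one gene per contig, both strands, optional
  short promoters to exercise edge truncation. Promoter backgrounds stay
  ACGT and are certified motif-free by scan-and-repair (mutate a base
  inside each residual hit, rescan) — whole-region rejection sampling
  would stall at 1 kb, where the W-box expectation is ~2 hits per strand.
  Planted elements may overlap if their IUPAC sets are jointly satisfiable
  (printed target tables do contain W-boxes overlapping by one base);
  infeasible overlaps are input errors. The generator re-scans after
  planting and fails loudly if ground truth is not exactly recoverable.
- **Ct tables** (`gen_ct_table`): reference gene constant up to noise;
  target Ct shifted by −log2(fold); replicate noise σ in cycles (default
  0.1, the scale of technical qPCR repeats; calibration tests use 0.2).
- **Counts** (`gen_counts`): NB(mu = base · libsize · fold, size = 1/φ)
  with per-sample library-size factors in [0.8, 1.2]; default dispersion
  φ = 0.05 (CV ≈ 0.23 at high expression, ordinary biological replicates).

What a green test does and does not establish: synthetic proteins have
clean backgrounds and exactly-spaced fingers, so detector recall there is
1 by construction — the tests establish coordinate bookkeeping, tolerance
boundaries and determinism, not sensitivity to divergent real domains.
Likewise the synthetic promoters prove scanner exactness, not that real
promoters are motif-free outside annotated sites.

# Numerical and calibration choices

- Power world for the RNA-seq caller: the fold-2 recovery property is
  tested on 50-gene panels (library-size estimation needs many flat genes;
  a 10-gene panel suffers visible compositional bias) with dispersion
  0.02 — per-sample CV ≈ 0.15, deep-sequencing scale, matching pooled
  single-run replicates. Under that world the analytic power of the
  prob ≥ 0.8 rule for a fold-2 gene with n = 3 exceeds 0.95 (measured
  0.98); with φ = 0.05 the same rule's power is only ≈ 0.85, which is a
  property of the rule, not a defect of the caller.
- Monte-Carlo scale-downs in tests are stated where they occur: Dunnett
  type-I simulation uses 50,000 draws per p-value (±~0.005 accuracy,
  noise-free for a [0.03, 0.07] band over 1000 simulations); bootstrap
  trees use 100–200 replicates in tests against the 1000 default.
- Every stochastic step takes an explicit integer seed; identical inputs,
  configuration and seed give byte-identical outputs (tested).
- Degenerate inputs have defined results: empty sequences align to all-gap
  columns with identity 0; zero pooled variance yields p = 1 (equal means)
  or p = 0 with a notice; zero control FPKM yields an infinite fold-change
  sentinel with a valid call.

# Limitations

- Group calls for single-domain CCHH proteins are only as good as the
  reference panel; the packaged panel is synthetic and illustrative.
- The progressive MSA is a standard guide-tree heuristic, not a ClustalX
  re-implementation; published tree topologies that depend on unpublished
  reference selections are out of scope.
- Genome-wide counts from the original *D. officinale* assembly
  (34,417 promoters; W-box tier sizes; GO/KEGG tallies; published DE gene
  lists) require external downloads and are deliberately not reproduced.
- FPKM is computed from supplied fragment counts; read mapping is out of
  scope.
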