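# wrkyscan

Genome-wide identification of WRKY transcription-factor family genes and a
survey of their potential target genes, as a reusable, tested R pipeline.

WRKY proteins are one of the largest plant transcription-factor families.
Each carries one or two ~60-residue WRKY domains: the heptapeptide
`WRKYGQK` (or a variant such as `WRKYGKK` or `WRKYATN`) followed by a
zinc-finger whose coordinating-residue spacing is written
`C-X{a}-C-X{b}-HX{H|C|Y}`. Domain count and finger type split the family
into group I (two domains), group II with subgroups IIa–IIe (one domain,
C2H2 finger), group III (one domain, C2HC finger), and a non-group (NG) for
members outside the canonical groups. WRKY factors bind the W-box,
consensus `(C/T)TGAC(C/T)` (IUPAC `YTGACY`), in target-gene promoters.

`wrkyscan` implements the full survey workflow for any proteome/genome:

- **Domain detection** — anchor-based heptapeptide search (W/K/Y fixed at
  positions 1/3/4, ≤3 mismatches elsewhere) plus zinc-finger spacing
  parsing; variant heptapeptides count only when a finger validates them.
- **Classification** — structural rules (2 domains → I; C2HC → III), then
  nearest-reference identity against a subgroup-labelled panel with a 0.35
  identity floor (below the floor → NG).
- **Phylogenetics** — progressive MSA (affine-gap Gotoh, BLOSUM62), exact
  Saitou–Nei Neighbor-Joining with deterministic tie-breaking, bootstrap
  support over alignment columns (default 1000 replicates).
- **Regulome** — 1-kb upstream regulatory regions from genome + GFF3
  (strand-aware, truncation-flagged), both-strand IUPAC motif scanning for
  the W-box and a PLACE-style catalog, target-gene calling by site-count
  tiers (≥1/≥2/≥3; targets need ≥3), exon/intron summaries.
- **Expression** — qPCR relative expression by 2^−ΔΔCt, Dunnett
  many-to-one tests (seeded Monte-Carlo multivariate-t), up/down calls at
  fold > 1.5 / ≤ 0.66 with p < 0.05; RNA-seq FPKM with validity > 10,
  fold ≥ 1.5 / ≤ 0.66 and bootstrap deviation probability ≥ 0.8.
- **Synthetic data** — generators for proteomes, annotated genomes with
  certified motif-free promoter backgrounds, Ct tables and
  negative-binomial count tables, each with recorded ground truth, so the
  entire pipeline is testable offline.

## Worked example

```r
library(wrkyscan)

sim <- gen_proteome(c(I = 1, IIc = 1, III = 1, NG = 1),
                    mutation_rate = 0.1, seed = 42)
identify_wrky(sim$proteins)
#>   protein_id length n_domains          motifs                    signatures
#> 1   SYN_I_01    155         2 WRKYGQK/WRKYGQK C-X4-C-X22-HXH/C-X4-C-X23-HXH
#> 2 SYN_IIc_01    112         1         WRKYGQK                C-X4-C-X23-HXH
#> 3 SYN_III_01     94         1         WRKYGQK                C-X7-C-X23-HXC
#> 4  SYN_NG_01     98         1         WRKYGRD                C-X4-C-X23-HXH

classify_proteome(sim$proteins)[, c(1, 2, 3, 5)]
#>   protein_id group          basis reference_identity
#> 1   SYN_I_01     I           rule                 NA
#> 2 SYN_IIc_01   IIc rule+reference          0.6376812
#> 3 SYN_III_01   III           rule                 NA
#> 4  SYN_NG_01    NG rule+reference          0.2405063
```

Reading the output: the group-I protein carries two heptapeptide+finger
blocks (`2` in `n_domains`, signatures tagged N/C in the per-domain table
from `assemble_domains()`); the group-III protein is called by its C2HC
finger alone; the IIc protein is 64% identical to a IIc panel entry (well
above the 0.35 floor); the NG protein's best panel identity is 0.24, below
the floor, so it stays outside the canonical groups — and its variant
motif `WRKYGRD` was accepted because a zinc finger validates it.

Promoter survey on a synthetic genome:

```r
g <- gen_genome(list(geneA = c(-106, -33, -127)), seed = 1)
regions <- extract_promoters(g$genome, g$annotation)     # 1-kb windows
hits <- scan_regions(regions)                            # W-box, both strands
call_targets(hits, regions$gene_id)
#>   gene_id wbox_count tier1 tier2 tier3 target     positions
#> 1   geneA          3  TRUE  TRUE  TRUE   TRUE -127,-106,-33
```

Three W-boxes (offsets relative to the ATG, −1 = the base just upstream)
put `geneA` in the ≥3-site tier, the threshold for calling a potential
WRKY target gene.

## Command line

A subcommand CLI (installed at `exec/wrky`, or call `wrky_cli()` directly)
covers the whole workflow: `identify`, `classify`, `tree`, `promoters`,
`scan`, `targets`, `structure`, `qpcr`, `rnaseq`, `simulate`. Column orders
are documented in [FORMATS.md](FORMATS.md).

## Scope

Desk-scale reproduction only: quantities that depend on the external
*D. officinale* assembly, annotation databases (GO/KEGG), read mapping, or
unpublished reference selections are out of scope; see the methods
vignette (`vignettes/wrky-family-pipeline.Rmd`) for the full model
description, parameter table and limitations.
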