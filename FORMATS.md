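# File formats

All tables are tab-separated with `#` comment lines; every report written by
the package starts with two comment lines naming the tool version and the
column order. Sequences are FASTA wrapped at 60 columns.

## Inputs

### Protein FASTA
Multi-record, wrapped or unwrapped. The record id is the first
whitespace-delimited token of the header.

### Genome FASTA + GFF3
Standard 9-column GFF3, 1-based closed coordinates. Features used:
`gene`, `mRNA`, `exon`, `CDS` with `ID=`/`Parent=` attributes. mRNA
features may be absent; `gene` + `CDS` is then treated as one transcript.
Malformed lines are reported by line number.

### Cis-element catalog (TSV)
Columns: `element_id`, `pattern` (IUPAC nucleotide codes), `category`.
PLACE's native format is not parsed; convert it to this layout (one row per
element, category of your choosing). The packaged default is
`inst/extdata/cis_elements.tsv`.

### Reference panel FASTA
Headers `>id|subgroup`, subgroup one of `I IIa IIb IIc IId IIe III`.
The packaged default (`reference_panel_synthetic.fasta`) is a synthetic
stand-in; replace it with curated domain sequences for real analyses.

### qPCR Ct table (TSV)
Columns: `gene_id`, `condition`, `replicate`, `ct`. The reference gene
(e.g. actin) appears as ordinary rows under its own `gene_id`.

### Count table (TSV)
Columns: `gene_id`, `sample`, `count` (fragments), `length` (nt).

## Outputs

| report | columns |
|---|---|
| identify | `protein_id length n_domains motifs signatures` |
| classify | `protein_id group basis best_reference reference_identity n_domains` |
| promoters (FASTA) | ids `<gene_id>\|promoter\|<length>` |
| scan hits | `gene_id element_id category pattern strand offset` |
| targets | `gene_id wbox_count tier1 tier2 tier3 target positions` |
| structure | `gene_id n_exons n_introns` |
| qpcr | `gene_id condition rq n_reps p call` |
| rnaseq | `gene_id mean_control mean_treated valid fold_change deviation_probability call` |
| tree | newick, bootstrap percentages as internal node labels |

Offsets are negative positions of a match's leftmost base in gene
orientation; `-1` is the base immediately 5' of the ATG. Strand is relative
to gene orientation. Ground truth from the simulators is JSON.
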