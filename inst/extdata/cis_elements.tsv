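# Illustrative PLACE-style cis-element catalog: element id, IUPAC pattern, category.
# The WBOX entry is the WRKY binding-site consensus (C/T)TGAC(C/T).
# Users substitute their own catalog converted from PLACE's native format
# (see FORMATS.md); this default covers the stress categories the promoter
# survey reports on.
element_id	pattern	category
WBOX	YTGACY	WRKY-binding
ABRELATERD1	ACGTG	ABA-responsive
ABREOSRAB21	TACGTGTC	ABA-responsive
LTRECOREATCOR15	CCGAC	low temperature-responsive
LTRE1HVBLT49	CCGAAA	low temperature-responsive
SURECOREATSULTR11	GAGAC	sulfur-responsive
SURE1STPAT21	AATAGAAAA	sulfur-responsive
MBS	CAACTG	drought-responsive
ARFAT	TGTCTC	auxin-responsive
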