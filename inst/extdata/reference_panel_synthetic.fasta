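>REF_I_a|I
WRKYGQKQGKGISFQPVCKMFQCMIGSEGQTGKPTFGPMTRMTPMHIHGSFFFPGQIFPKAMAIVLGT
>REF_I_b|I
WRKYGQKSEQAINATINCDVFGCEVLFTRQTQIPRTMVAMKGGDIHAHFINFQDQDVKNSSGSMSLVV
>REF_IIa_a|IIa
WRKYGQKNVGRFMKKDSCREQGICVEQTVAKIMEMRGATDIAPGFSVHVHGLVRKQPETTDVPIALPLVP
>REF_IIa_b|IIa
WRKYGQKDTKVVLEMRLCIMVGKCINGIFMVISTNRIVTVSLFAIALHQHAMLEIQTSITLIPSIPKRTM
>REF_IIb_a|IIb
WRKYGQKLESKQPVAPGCSMEPGCPFIPPEDLSVEILAGKITPTLGRHLHFADDSFEGSEGESVMSNIME
>REF_IIb_b|IIb
WRKYGQKPEFGSDPPVVCTPIVTCIDETFIATNALLTQMMDISVESLHRHKGKFKAIRVPKNDMIKPSRT
>REF_IIc_a|IIc
WRKYGQKFNKRETAEMKCKETKCLGVANKKDGAGQFLGLVMMLVTPHKHQIPPIILKVFNELGTSPIVL
>REF_IIc_b|IIc
WRKYGQKMKTQVSTKANCVVIMCAFKPDNINQTRMRRSINQAFQFNHRHGQNSVIMETRTGDNIIPNMI
>REF_IId_a|IId
WRKYGQKEAADDPTNLGCQIMDICLMTGQMQQGRAIEGKPLVLERIDHAHKVKVTRFGQEDRMMLQIIMA
>REF_IId_b|IId
WRKYGQKQTSNFMIALRCATVMFCFEERPELNLKLLENLVTFDPQNKHGHASARIIPKPANVVTPTQTGM
>REF_IIe_a|IIe
WRKYGQKRPAQRMQDTKCASKDPCFNDGFRLVIFLKNRGLPDKVLPPHVHSNEDNATSESRMTATRMQET
>REF_IIe_b|IIe
WRKYGQKAQEVPKIDLICVTNMTCMFRKRILNSVAKMNPFLDQGDAKHNHIIMTPDQPQILAVINPQLGA
>REF_III_a|III
WRKYGQKAVTKQIMPKFCDKIPNRACEGDTRQSPKDMQQKGVTTKVPNKHACNNVNMSDKAKETKLAMDQIS
>REF_III_b|III
WRKYGQKFIAVFFANQMCSPTSIGGCPGSSNSMMERKAQVMPAGLSSRVHKCVKGQMESFVTPISQSSLRQA
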