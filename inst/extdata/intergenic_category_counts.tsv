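# Per-stage intergenic transcribed-region classification counts,
# transcribed from the published tabulation (panel C).
condition	flanking_ucsc	ensembl_overlap	ensembl_flanking	unexplained	total
E11.5	528	1981	587	4312	7408
E13.5	526	1970	576	4399	7471
E15.5	537	1994	592	4354	7477
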