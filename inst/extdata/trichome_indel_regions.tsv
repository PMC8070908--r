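Chrom	Start	End	NumberOfGenes
A07	1892096	1992096	13
A10	2673013	2773013	23
Scaffold000100	764907	864907	9
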