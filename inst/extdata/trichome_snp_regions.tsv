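Chrom	Start	End	NumberOfGenes
Scaffold000100	160071	260071	6
Scaffold001011	-49220	50780	0
Scaffold004266	-49807	50193	0
A06	22044767	22246745	30
A06	23704762	24097454	74
Scaffold000169	132175	132181	0
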