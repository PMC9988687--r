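probe	gene
ILMN_1664047	CACNA1E
ILMN_1790100	DDIAS
ILMN_1701837	KLHL2
ILMN_1684497	PYROXD2
ILMN_1775380	SMOX
ILMN_1802888	ZNF185
ILMN_3236239	LINC02035
ILMN_1796423	CLIC3
ILMN_1801216	S100P
ILMN_2058782	IFI27
ILMN_1898691	TIGIT
ILMN_2379599	CD163
ILMN_1756928	RTN1
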