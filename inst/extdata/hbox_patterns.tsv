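subfamily	box	pattern
FAB2	1	WT(S)AE(K)ENR(H)HG
FAB2	2	DAA(S)DEKRHE
FAD2	1	WV(I)IA(G)HECGHHAFS
FAD2	2	FSWKYS(T)HR(Q)RHHSNTT
FAD2	3	DTHVXHHLFP(S)
FAD2	3core	HVXHH
FAD3/7/8	1	WALFVLGHDCGHGSFS
FAD3/7/8	2	YHGWRISHRTHHQNHGHHHDIGT
FAD3/7/8	3	HVIHHLFPQIPHYHL
FAD6	1	FFVIGHDCAHRKSFS
FAD6	2	EPWRFKHDRHHAKTN
FAD6	3	HDINVHVPHHISPR
SLD1	1	GHDSGHH
SLD1	2	WWKCNHNTHHIACNS
SLD1	3	LDGGLQFQIEHHLFPRLPR
DES1	1	NLFLAIHELSHNLAFF
DES1	2	QKYHLEHHRFQGVDG
DES1	3	IDHVGYHNEHHDFPRIPG
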