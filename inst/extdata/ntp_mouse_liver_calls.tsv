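chemical	short_name	liver_tumor_call	p_reported
1-Amino-2,4-dibromoanthraquinone	ADBQ	Yes	NA
Benzofuran	BFUR	Yes	NA
Methylene Chloride	MECL	Yes	NA
N-Methylolacrylamide	MACR	Yes	NA
1,5-Naphthalenediamine	NAPD	Yes	NA
Tris(2,3-dibromopropyl)phosphate	TDPP	Yes	NA
2,2-Bis(bromomethyl)-1,3-propanediol	BBMP	No	NA
1,2-Dibromoethane	DBET	No	NA
Ethylene Oxide	ETOX	No	NA
Naphthalene	NPTH	No	NA
Vanadium Pentoxide	VANP	No	NA
Benzene	BENZ	Eq	0.075
Coumarin	COUM	Eq	0.084
1,2,3-Trichloropropane	TCPN	Yes	NA
1,4-Dichlorobenzene	DCBZ	Yes	NA
Propylene glycol mono-t-butyl ether	PGBE	Yes	NA
Tetrafluoroethylene	TFEL	Yes	NA
2-Chloromethylpyridine hydrochloride	CMPH	No	NA
Diazinon	DIAZ	No	NA
Iodoform	IODO	No	NA
Malathion	MALA	No	NA
N-(1-naphthyl) ethylenediamine dihydrochloride	NEDD	No	NA
4-Nitroanthranilic acid	NAAC	No	NA
Pentachloronitrobenzene	PCNB	No	NA
Tetrafluoroethane	TFEA	No	NA
Trichlorofluoromethane	TCFM	No	NA
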