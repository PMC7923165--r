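accession	symbol	sites	evidence	direction
O00221	NFKBIE	155	phosphosite	up
P16885	PLCG2	1217	phosphosite	up
P43405	SYK	352	phosphosite	up
P05771	PRKCB	507	phosphosite	up
P49023	PXN	409;468	phosphosite	up
O14950	MYL12B	143	phosphosite	up
Q9NZN5	ARHGEF12	1232	phosphosite	up
O14974	PPP1R12A	446	phosphosite	up
Q9Y281	CFL2	89*	phosphosite	up
P60709	ACTB	240	phosphosite	up
P23528	CFL1	89*	phosphosite	up
Q9Y2X7	GIT1	598;545	phosphosite	up
P15311	EZR	424	phosphosite	up
P19105	MYL12A	142	phosphosite	up
P00533	EGFR	1069	phosphosite	up
Q9NRY4	ARHGAP35	1087	phosphosite	up
Q9UQB8	BAIAP2	505	phosphosite	up
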