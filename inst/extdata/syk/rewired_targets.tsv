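symbol	accession	target_in	present_in
ARFGAP1	Q8N6T3	MCF7;MDA231	MCF7;MDA231
BLK	P51451	DG75	MCF7;DG75
CBL	P22681	MCF7;MDA231	MCF7;MDA231;DG75
CDK1	P06493	DG75	MCF7;MDA231;DG75
CLTA	P09496	MCF7	MCF7;MDA231;DG75
COPS4	Q9BT78	MCF7	MCF7;DG75
COPS8	Q99627	MCF7	MCF7;DG75
DNMT1	P26358	MDA231	MDA231
EPS15L1	Q9UBC2	MCF7	MCF7;MDA231
ESPL1	Q14674	MDA231	MCF7;MDA231;DG75
FIP1L1	Q6UN15	DG75	DG75
GBF1	Q92538	MDA231	MDA231
KPNA4	O00629	MDA231	MDA231
MTMR6	Q9Y217	MDA231	MDA231
NFKB2	Q00653	DG75	MCF7;MDA231;DG75
PTDSS1	P48651	MDA231	MDA231
PYGB	P11216	MDA231	MCF7;MDA231
REEP4	Q9H6H4	MDA231	MDA231
RRP8	O43159	DG75	DG75
SAP30BP	Q9UHR5	MDA231	MDA231
SF3B1	O75533	MDA231	MDA231
SKP1	P63208	MCF7	MCF7;DG75
STAM	Q92783	MCF7	MCF7;MDA231
SUPT5H	O00267	MDA231	MDA231
TFRC	P02786	MDA231	MCF7;MDA231
TRIP10	Q15642	MCF7	MCF7;DG75
TYMS	P04818	MDA231	MCF7;MDA231
UPF1	Q92900	MDA231;DG75	MCF7;MDA231;DG75
VAMP8	Q9BV40	MCF7	MCF7;MDA231
YAP1	P46937	MDA231	MCF7;MDA231
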