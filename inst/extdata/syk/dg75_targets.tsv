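accession	symbol	sites	evidence	direction
O00221	NFKBIE	155	phosphosite	up
Q13469	NFATC2	752	phosphosite	up
P29350	PTPN6	536	phosphosite	up
P16885	PLCG2	759*;550;858;1245	phosphosite	up
Q06187	BTK	551*	phosphosite	up
P27361	MAPK3	204	phosphosite	up
O15357	INPPL1	1135	phosphosite	up
Q6ZUJ8	PIK3AP1	694	phosphosite	up
P11912	CD79A	210	phosphosite	up
P28482	MAPK1	187	phosphosite	up
P49023	PXN	88	phosphosite	up
Q9Y281	CFL2	89	phosphosite	up
P60709	ACTB	240	phosphosite	up
P23528	CFL1	68;89	phosphosite	up
P63261	ACTG1	240	phosphosite	up
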