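accession	symbol	sites	evidence	direction
P29350	PTPN6		presence	up
P01111	NRAS		presence	up
P63000	RAC1		presence	up
P62993	GRB2		presence	up
Q04206	RELA		presence	up
O15357	INPPL1		presence	up
P28482	MAPK1		presence	up
Q9Y6W5	WASF2		presence	up
Q9NZN5	ARHGEF12		presence	up
P12814	ACTN1		presence	up
Q14155	ARHGEF7		presence	up
P62140	PPP1CB		presence	up
P62136	PPP1CA		presence	up
P15311	EZR		presence	up
Q13576	IQGAP2		presence	up
P19105	MYL12A		presence	up
O43707	ACTN4		presence	up
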