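hsa04662	B cell receptor signaling pathway	O00221	Q13469	P29350	P01111	P63000	P62993	P16885	Q06187	P27361	Q04206	P43405	O15357	P05771	Q6ZUJ8	P11912	P28482
hsa04810	Regulation of actin cytoskeleton	P49023	Q9Y6W5	O14950	Q9NZN5	P01111	P12814	P35241	O14974	Q9Y281	Q14155	P62140	P28482	P60709	P23528	Q9Y2X7	P62136	P63000	P15311	Q13576	P27361	P19105	P00533	O43707	Q9NRY4	P63261	Q9UQB8
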