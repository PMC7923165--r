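P43405	phosphorylates	Q06187
P43405	phosphorylates	P16885
P43405	phosphorylates	P15311
P11912	activates	P43405
P16885	activates	P05771
Q06187	phosphorylates	P16885
P05771	activates	P27361
P05771	activates	P28482
P62993	activates	P01111
P01111	activates	P27361
P01111	activates	P28482
P63000	activates	P49023
P29350	dephosphorylates	P43405
P28482	phosphorylates	P49023
P15311	interacts	P63000
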