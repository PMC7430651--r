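name	motif
ACS_core	TTTATGTTTA
ABF1	TCACACGACG
RAP1	ACACCCATACAT
REB1	TTACCCGG
MCB	ACGCGT
SCB	CACGAAAA
TATA	TATAAA
GCR1	CTTCC
STRE	CCCCT
PDS	AGGGAT
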