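ATF3	pd	ICA1
ATF3	pd	ID1
ATF3	pd	TCF12
ATF3	pd	TBL1X
ATF3	pd	RNF14
ID2	pd	ID1
ID2	pd	TCF12
NFKB1	pd	RELA
RELA	pp	TBL1X
ICA1	pp	PTPRN
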