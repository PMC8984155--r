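pair_id	partner_a	partner_b	a_is_receptor	b_is_receptor
MIF_TNFRSF14	MIF	TNFRSF14	False	True
LCK_CD8A	LCK	CD8A	False	True
CD58_CD2	CD58	CD2	False	True
CTLA4_CD86	CD86	CTLA4	False	True
HGF_MET	HGF	MET	False	True
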