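PI_11	reconstructed 11-gene proliferation index panel	TYMS	TK1	CCNB1	CCNB2	MKI67	BIRC5	RRM2	TOP2A	CKS1B	ASPM	AURKA
CGA_27	reconstructed panel of 27 hematological cancer germline antigens	MAGEA1	MAGEA3	MAGEA4	MAGEA6	MAGEA12	MAGEB1	MAGEB2	MAGEC1	MAGEC2	CTAG1B	CTAG2	GAGE1	GAGE2A	GAGE12F	SSX1	SSX2	SSX4	PRAME	PASD1	CT45A1	CT47A1	CTCFL	SPANXB1	TEX14	ADAM2	PAGE1	HORMAD1
NFKB_INDEX	reconstructed NFkB activity index panel	BIRC3	TNFAIP3	NFKB2	NFKBIA	NFKBIE	RELB	CD74	PLEK	MALT1	WNT10A	IL2RG
HLA_I	HLA class I score panel	HLA-A	HLA-B	HLA-C	B2M
HLA_II	HLA class II score panel	HLA-DRA	HLA-DRB1	HLA-DPA1	HLA-DPB1	HLA-DQA1	HLA-DQB1	CD74
ABC_TRANSPORTERS	ABC transporter panel	ABCA1	ABCB1	ABCB9	ABCC1	ABCC3	ABCC4	ABCC5	ABCC10	ABCD1	ABCE1	ABCF1	ABCG1	ABCG2
EXPORTINS	nuclear exportin panel	XPO1	XPO4	XPO5	XPO6	XPO7	XPOT	CSE1L
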