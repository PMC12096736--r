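gene	is_mito	complex	module
MT-ND1	TRUE	CI	NA
MT-ND2	TRUE	CI	NA
MT-ND3	TRUE	CI	NA
MT-ND4	TRUE	CI	NA
MT-ND4L	TRUE	CI	NA
MT-ND5	TRUE	CI	NA
MT-ND6	TRUE	CI	NA
NDUFS1	TRUE	CI	N-module
NDUFS2	TRUE	CI	NA
NDUFS3	TRUE	CI	NA
NDUFS4	TRUE	CI	N-module
NDUFS5	TRUE	CI	NA
NDUFS6	TRUE	CI	N-module
NDUFS7	TRUE	CI	NA
NDUFS8	TRUE	CI	NA
NDUFV1	TRUE	CI	N-module
NDUFV2	TRUE	CI	N-module
NDUFV3	TRUE	CI	N-module
NDUFA1	TRUE	CI	NA
NDUFA2	TRUE	CI	N-module
NDUFA3	TRUE	CI	NA
NDUFA5	TRUE	CI	NA
NDUFA6	TRUE	CI	N-module
NDUFA7	TRUE	CI	N-module
NDUFA8	TRUE	CI	NA
NDUFA9	TRUE	CI	NA
NDUFA10	TRUE	CI	NA
NDUFA11	TRUE	CI	NA
NDUFA12	TRUE	CI	N-module
NDUFA13	TRUE	CI	NA
NDUFAB1	TRUE	CI	N-module
NDUFB1	TRUE	CI	NA
NDUFB2	TRUE	CI	NA
NDUFB3	TRUE	CI	NA
NDUFB4	TRUE	CI	NA
NDUFB5	TRUE	CI	NA
NDUFB6	TRUE	CI	NA
NDUFB7	TRUE	CI	NA
NDUFB8	TRUE	CI	NA
NDUFB9	TRUE	CI	NA
NDUFB10	TRUE	CI	NA
NDUFB11	TRUE	CI	NA
NDUFC1	TRUE	CI	NA
NDUFC2	TRUE	CI	NA
SDHA	TRUE	CII	NA
SDHB	TRUE	CII	NA
SDHC	TRUE	CII	NA
SDHD	TRUE	CII	NA
UQCRC1	TRUE	CIII	NA
UQCRC2	TRUE	CIII	NA
CYC1	TRUE	CIII	NA
UQCRFS1	TRUE	CIII	NA
MT-CYB	TRUE	CIII	NA
UQCRB	TRUE	CIII	NA
UQCRQ	TRUE	CIII	NA
UQCRH	TRUE	CIII	NA
UQCR10	TRUE	CIII	NA
UQCR11	TRUE	CIII	NA
MT-CO1	TRUE	CIV	NA
MT-CO2	TRUE	CIV	NA
MT-CO3	TRUE	CIV	NA
COX4I1	TRUE	CIV	NA
COX4I2	TRUE	CIV	NA
COX5A	TRUE	CIV	NA
COX5B	TRUE	CIV	NA
COX6A1	TRUE	CIV	NA
COX6A2	TRUE	CIV	NA
COX6B1	TRUE	CIV	NA
COX6C	TRUE	CIV	NA
COX7A1	TRUE	CIV	NA
COX7A2	TRUE	CIV	NA
COX7A2L	TRUE	CIV	NA
COX7B	TRUE	CIV	NA
COX7C	TRUE	CIV	NA
COX8A	TRUE	CIV	NA
COX8C	TRUE	CIV	NA
NDUFA4	TRUE	CIV	NA
ATP5F1A	TRUE	CV	NA
ATP5F1B	TRUE	CV	NA
ATP5F1C	TRUE	CV	NA
ATP5F1D	TRUE	CV	NA
ATP5F1E	TRUE	CV	NA
ATP5PB	TRUE	CV	NA
ATP5PD	TRUE	CV	NA
ATP5PF	TRUE	CV	NA
ATP5PO	TRUE	CV	NA
ATP5MC1	TRUE	CV	NA
ATP5MC2	TRUE	CV	NA
ATP5MC3	TRUE	CV	NA
ATP5ME	TRUE	CV	NA
ATP5MF	TRUE	CV	NA
ATP5MG	TRUE	CV	NA
ATP5MJ	TRUE	CV	NA
MT-ATP6	TRUE	CV	NA
MT-ATP8	TRUE	CV	NA
MRPL1	TRUE	mtLSU	NA
MRPL2	TRUE	mtLSU	NA
MRPL3	TRUE	mtLSU	NA
MRPL4	TRUE	mtLSU	NA
MRPL9	TRUE	mtLSU	NA
MRPL10	TRUE	mtLSU	NA
MRPL11	TRUE	mtLSU	NA
MRPL12	TRUE	mtLSU	NA
MRPL13	TRUE	mtLSU	NA
MRPL14	TRUE	mtLSU	NA
MRPL15	TRUE	mtLSU	NA
MRPL16	TRUE	mtLSU	NA
MRPL17	TRUE	mtLSU	NA
MRPL18	TRUE	mtLSU	NA
MRPL19	TRUE	mtLSU	NA
MRPL20	TRUE	mtLSU	NA
MRPL21	TRUE	mtLSU	NA
MRPL22	TRUE	mtLSU	NA
MRPL23	TRUE	mtLSU	NA
MRPL24	TRUE	mtLSU	NA
MRPL27	TRUE	mtLSU	NA
MRPL28	TRUE	mtLSU	NA
MRPL30	TRUE	mtLSU	NA
MRPL32	TRUE	mtLSU	NA
MRPL33	TRUE	mtLSU	NA
MRPL34	TRUE	mtLSU	NA
MRPL35	TRUE	mtLSU	NA
MRPL36	TRUE	mtLSU	NA
MRPL37	TRUE	mtLSU	NA
MRPL38	TRUE	mtLSU	NA
MRPL39	TRUE	mtLSU	NA
MRPL40	TRUE	mtLSU	NA
MRPL41	TRUE	mtLSU	NA
MRPL42	TRUE	mtLSU	NA
MRPL43	TRUE	mtLSU	NA
MRPL44	TRUE	mtLSU	NA
MRPL45	TRUE	mtLSU	NA
MRPL46	TRUE	mtLSU	NA
MRPL47	TRUE	mtLSU	NA
MRPL48	TRUE	mtLSU	NA
MRPL49	TRUE	mtLSU	NA
MRPL50	TRUE	mtLSU	NA
MRPL51	TRUE	mtLSU	NA
MRPL52	TRUE	mtLSU	NA
MRPL53	TRUE	mtLSU	NA
MRPL54	TRUE	mtLSU	NA
MRPL55	TRUE	mtLSU	NA
MRPL56	TRUE	mtLSU	NA
MRPL57	TRUE	mtLSU	NA
MRPL58	TRUE	mtLSU	NA
MRP63	TRUE	mtLSU	NA
GADD45GIP1	TRUE	mtLSU	NA
DAP3	TRUE	mtSSU	NA
MRPS2	TRUE	mtSSU	NA
MRPS5	TRUE	mtSSU	NA
MRPS6	TRUE	mtSSU	NA
MRPS7	TRUE	mtSSU	NA
MRPS9	TRUE	mtSSU	NA
MRPS10	TRUE	mtSSU	NA
MRPS11	TRUE	mtSSU	NA
MRPS12	TRUE	mtSSU	NA
MRPS14	TRUE	mtSSU	NA
MRPS15	TRUE	mtSSU	NA
MRPS16	TRUE	mtSSU	NA
MRPS17	TRUE	mtSSU	NA
MRPS18	TRUE	mtSSU	NA
MRPS21	TRUE	mtSSU	NA
MRPS22	TRUE	mtSSU	NA
MRPS23	TRUE	mtSSU	NA
MRPS24	TRUE	mtSSU	NA
MRPS25	TRUE	mtSSU	NA
MRPS26	TRUE	mtSSU	NA
MRPS27	TRUE	mtSSU	NA
MRPS28	TRUE	mtSSU	NA
MRPS30	TRUE	mtSSU	NA
MRPS31	TRUE	mtSSU	NA
MRPS33	TRUE	mtSSU	NA
MRPS34	TRUE	mtSSU	NA
MRPS35	TRUE	mtSSU	NA
MRPS36	TRUE	mtSSU	NA
MRPS18A	TRUE	mtSSU	NA
MRPS18B	TRUE	mtSSU	NA
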