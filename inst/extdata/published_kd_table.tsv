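construct	domain	ligand	model	kd	kd_sd
US-WT	UIM	Ub	1to1	86	31
US-WT	SH3	Ub	1to1	267	119
US-WT	UIM	Lys63-Ub2	2to1	78	59
US-WT	SH3	Lys63-Ub2	2to1	60	28
US-D1	UIM	Ub	1to1	148	60
US-D1	SH3	Ub	1to1	394	127
US-D1	UIM	Lys63-Ub2	2to1	137	57
US-D1	SH3	Lys63-Ub2	2to1	253	163
US-D2	UIM	Ub	1to1	203	91
US-D2	SH3	Ub	1to1	669	234
US-D2	UIM	Lys63-Ub2	2to1	99	50
US-D2	SH3	Lys63-Ub2	2to1	483	196
US-D3	SH3	Ub	1to1	266	96
US-D3	SH3	Lys63-Ub2	1to1	39	22
US-D4	SH3	Ub	1to1	158	79
US-D4	SH3	Lys63-Ub2	1to1	97	49
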