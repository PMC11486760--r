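sample_id	age	tumor_size_cm	histologic_type	histologic_grade	er	pr	her2	ki67	ki67_category	molecular_type	slnm	cin_group	arm_changes
1	64	1.6	IDC	I	positive	positive	negative	<14%	<14%	Luminal A	yes	Low	yes
2	66	3.0	IDC	II	positive	positive	positive	<14%	<14%	Luminal B	yes	High	yes
3	40	1.3	IDC	III	negative	negative	negative	>30%	>=14%	TNBC	yes	High	yes
4	46	1.5	IDC	II	positive	positive	negative	>14%	>=14%	Luminal B	yes	High	yes
5	68	2.0	IDC	II	positive	positive	negative	<14%	<14%	Luminal A	yes	High	yes
6	30	1.2	ILC	Other	positive	positive	negative	>30%	>=14%	Luminal B	yes	High	yes
7	64	4.0	IDC	II	positive	negative	negative	>14%	>=14%	Luminal B	yes	High	yes
8	79	2.6	ILC	Other	positive	positive	negative	<14%	<14%	Luminal A	yes	High	yes
9	37	5.0	IDC	II	positive	positive	negative	>30%	>=14%	Luminal B	yes	Low	yes
10	80	1.6	IDC	I	positive	positive	negative	<14%	<14%	Luminal A	yes	High	yes
11	61	1.5	IDC	I	positive	positive	negative	<14%	<14%	Luminal A	yes	High	yes
12	44	5.0	IMC	Other	positive	positive	negative	>14%	>=14%	Luminal B	yes	Low	yes
13	58	1.0	IDC	II	positive	positive	negative	>20%	>=14%	Luminal B	yes	High	yes
14	49	1.5	IDC	II	positive	positive	negative	<14%	<14%	Luminal A	yes	Low	no
15	72	1.8	IDC	II	positive	positive	negative	<14%	<14%	Luminal A	yes	High	no
16	73	2.2	IDC	II	positive	positive	negative	>14%	>=14%	Luminal B	yes	Low	no
17	64	2.5	NC	Other	positive	positive	negative	<14%	<14%	Luminal A	yes	High	no
18	69	2.2	IDC	II	negative	negative	positive	70%	>=14%	Over-HER2	yes	High	no
19	81	1.5	IDC	I	positive	positive	negative	15%	>=14%	Luminal B	yes	Low	no
20	73	3.0	IDC	II	positive	positive	positive	15%	>=14%	Luminal B	yes	High	no
21	54	3.5	IDC	III	negative	negative	negative	65%	>=14%	TNBC	yes	Low	no
22	51	3.5	IDC	II	positive	positive	negative	12%	<14%	Luminal A	yes	Low	no
23	71	1.5	ILC	Other	positive	positive	negative	8%	<14%	Luminal A	yes	High	no
24	71	1.5	IMC	Other	positive	positive	negative	5%	<14%	Luminal A	yes	High	no
25	68	0.9	DCIS	Other	positive	positive	negative	5%	<14%	Luminal A	no	Low	no
26	80	1.5	IDC	I	positive	positive	negative	15%	>=14%	Luminal B	no	Low	no
27	69	2.0	IDC	II	positive	negative	negative	8%	<14%	Luminal B	no	Low	no
28	75	1.5	DCIS	Other	negative	negative	negative	3%	<14%	TNBC	no	Low	no
29	40	2.5	IBCM	Other	negative	negative	negative	80%	>=14%	TNBC	no	Low	no
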