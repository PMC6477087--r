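patient_id	group	age	sex	laterality	invasiveness
C1	control	12 Y	Unknown	N/A	N/A
1	tumor	6 Y	Male	OD (IIRC Grade E)	Invasive
2	tumor	3 Y	Male	OS (IIRC Grade E)	Non-Invasive
C2	control	5 Y	Unknown	N/A	N/A
3	tumor	2 Y	Female	OD (IIRC Grade E)	Non-Invasive
4	tumor	3 Y	Female	OD (IIRC Grade D)	Non-Invasive
5	tumor	1 Y	Female	OD	Invasive
6	tumor	3 Y	Male	OS (IIRC Grade D)	Non-Invasive
C3	control	22 Y	Unknown	N/A	N/A
7	tumor	8 Months	Male	OD (IIRC Grade E)	Invasive
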