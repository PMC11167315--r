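T1	Patient 4 15	Maria Lopez
T2	Patient 16 30	saw John Smith
T3	Occupation 46 60	retired welder
T4	Hospital 65 79	Mercy Hospital
T5	Date 83 92	3/15/2019
T6	Phone 99 113	(555) 012-3456
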