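T1	Provider 4 15	Maria Lopez
T2	Patient 20 30	John Smith
T3	Age 34 36	92
T4	Occupation 46 60	retired welder
T5	Hospital 65 79	Mercy Hospital
T6	Date 83 92	3/15/2019
T7	Phone 99 113	(555) 012-3456
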