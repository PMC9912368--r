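system	code	dm_type
READ_V2	C10..	GENERIC
READ_V2	C100.	GENERIC
READ_V2	C108.	T1D
READ_V2	C109.	T2D
READ_V2	C1090	T2D
CTV3	XE10E	GENERIC
CTV3	X40J4	T2D
CTV3	X40J5	T1D
CTV3	X40JX	T2D
ICD10	E10	T1D
ICD10	E11	T2D
ICD10	E14	GENERIC
SELF_REPORT_ILLNESS	1220	GENERIC
SELF_REPORT_ILLNESS	1222	T1D
SELF_REPORT_ILLNESS	1223	T2D
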