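system	code
READ_V2	C10..
READ_V2	C100.
READ_V2	C108.
READ_V2	C109.
READ_V2	C1090
READ_V2	C10y.
READ_V2	66A..
READ_V2	66A4.
READ_V2	F420.
READ_V2	F4200
CTV3	XE10E
CTV3	X40J4
CTV3	X40J5
CTV3	X40JX
TPP_LOCAL	Y1234
READ_V2	H33..
READ_V2	44g1.
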