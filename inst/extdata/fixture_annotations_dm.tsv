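code	action
C10..	keep
C100.	keep
C108.	keep
C109.	keep
C1090	keep
C10y.	drop
66A..	date_only
66A4.	date_only
F420.	drop
F4200	drop
XE10E	keep
X40J4	keep
X40J5	keep
X40JX	keep
Y1234	date_only
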