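read2_code	ctv3_code
C10..	XE10E
C108.	X40J5
C109.	X40J4
C11..	X40JX
66A4.	Y7777
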