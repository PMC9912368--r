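biomarker	unit	factor
GLUCOSE	mg/dL	0.0555
SERUM_CREATININE	mg/dL	88.4
TOTAL_CHOL	mg/dL	0.02586
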