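system	code	description
READ_V2	C10..	Diabetes mellitus
READ_V2	C100.	Diabetes mellitus with no mention of complication
READ_V2	C108.	Type 1 diabetes mellitus
READ_V2	C109.	Type 2 diabetes mellitus
READ_V2	C1090	Type 2 diabetes mellitus with renal complications
READ_V2	C10y.	Diabetes mellitus resolved
READ_V2	C11..	Other specified diabetes mellitus
READ_V2	L180.	Gestational diabetes mellitus
READ_V2	66A..	Diabetic monitoring
READ_V2	66A4.	Diabetic on insulin
READ_V2	F420.	Diabetic retinopathy
READ_V2	F4200	Background diabetic retinopathy
READ_V2	K05..	Chronic renal failure
READ_V2	K01..	Nephrotic syndrome
READ_V2	H33..	Asthma
READ_V2	H330.	Extrinsic asthma
READ_V2	G20..	Essential hypertension
READ_V2	44g1.	Plasma glucose level
READ_V2	42W5.	HbA1c level (IFCC)
READ_V2	46N4.	Urine albumin concentration
READ_V2	46M7.	Urine creatinine concentration
READ_V2	44J3.	Serum creatinine level
READ_V2	2469.	O/E Systolic blood pressure reading
READ_V2	246A.	O/E Diastolic blood pressure reading
READ_V2	44P..	Serum cholesterol level
READ_V2	44P5.	Serum HDL cholesterol level
READ_V2	44P6.	Serum LDL cholesterol level
READ_V2	44Q..	Serum triglycerides level
READ_V2	46TC.	Urine albumin:creatinine ratio
CTV3	XE10E	Diabetes mellitus
CTV3	X40J4	Type 2 diabetes mellitus
CTV3	X40J5	Type 1 diabetes mellitus
CTV3	X40JX	Maturity onset DM
CTV3	XE2eD	Hypertensive disorder
ICD10	E10	Type 1 diabetes mellitus
ICD10	E11	Type 2 diabetes mellitus
ICD10	E14	Unspecified diabetes mellitus
ICD10	I21	Acute myocardial infarction
ICD10	I63	Cerebral infarction
ICD10	I200	Unstable angina
ICD10	N18	Chronic kidney disease
ICD10	N00	Acute nephritic syndrome
ICD10	H360	Diabetic retinopathy
ICD10	H353	Degeneration of macula and posterior pole
OPCS4	K49	Transluminal balloon angioplasty of coronary artery
SELF_REPORT_ILLNESS	1220	diabetes
SELF_REPORT_ILLNESS	1222	type 1 diabetes
SELF_REPORT_ILLNESS	1223	type 2 diabetes
SELF_REPORT_ILLNESS	1065	hypertension
TPP_LOCAL	Y1234	Diabetes annual review
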