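protein_id	organism	system	complex	subunit	domains	inferred
CHC1_YEAST	yeast	CCV	triskelion	heavy chain	PF01394;PF09268;PF13838;PF00637;PS50236	false
AP1G1_YEAST	yeast	CCV	AP1	γ	PS00435	false
AP1B1_YEAST	yeast	CCV	AP1	β1	PF01602	false
AP2B2_YEAST	yeast	CCV	AP2	β2	PS00867	false
AP1B12_ARATH	arabidopsis	CCV	AP2	β2	PF01602	true
AP2M2_HUMAN	human	CCV	AP2	μ2	PF00928	true
AP3D_HUMAN	human	CCV	AP3	δ	PF01602	true
AP3B3_HUMAN	human	CCV	AP3	β3	PF01602	true
AP3M3_ARATH	arabidopsis	CCV	AP3	μ3	PF00928	true
AP4B4_HUMAN	human	CCV	AP4	β4	PF01602;PF09066	true
AP4E_HUMAN	human	CCV	AP4	ε	PF01602	true
AP5M5_HUMAN	human	CCV	AP5	μ5	PF00928	true
COPA_ARATH	arabidopsis	COPI	B-COPI	α	PS50082;PS50294;PS00678	true
COPB2_ARATH	arabidopsis	COPI	B-COPI	β′	PS50294;PS50082	false
COPE_ARATH	arabidopsis	COPI	B-COPI	ε	PF04733	false
COPD_HUMAN	human	COPI	F-COPI	δ	PF00928	true
COPZ_YEAST	yeast	COPI	F-COPI	ζ	PS50234	true
ARFA_ARATH	arabidopsis	GTPase	ArfA	Arf	PF00025	true
ARFB_ARATH	arabidopsis	GTPase	ArfB	Arf	PF00025	true
ARFD_ARATH	arabidopsis	GTPase	ArfD	Arf	PF00025	true
ARFB2_ARATH	arabidopsis	GTPase	ArfB2	Arf	PF00025	true
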