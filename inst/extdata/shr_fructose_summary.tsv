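panel	variable	unit	group	mean	sem	n	sig_vs_H	sig_vs_HO
metabolic	body_weight	g	H	197	2	8	FALSE	FALSE
metabolic	body_weight	g	HO	264	3	8	TRUE	FALSE
metabolic	body_weight	g	FHO	261	2	8	TRUE	FALSE
metabolic	adipose_tissue	g	H	1.91	0.16	8	FALSE	FALSE
metabolic	adipose_tissue	g	HO	2.96	0.45	8	FALSE	FALSE
metabolic	adipose_tissue	g	FHO	5.25	0.39	8	TRUE	TRUE
metabolic	glucose	mg/dL	H	83	5.0	8	FALSE	FALSE
metabolic	glucose	mg/dL	HO	84	2.0	8	FALSE	FALSE
metabolic	glucose	mg/dL	FHO	92	2.1	8	FALSE	FALSE
metabolic	triglyceride	mg/dL	H	132	4.0	8	FALSE	FALSE
metabolic	triglyceride	mg/dL	HO	125	6.4	8	FALSE	FALSE
metabolic	triglyceride	mg/dL	FHO	160	8.0	8	TRUE	TRUE
metabolic	kitt	%/min	H	4.15	0.26	8	FALSE	FALSE
metabolic	kitt	%/min	HO	4.69	0.33	8	FALSE	FALSE
metabolic	kitt	%/min	FHO	3.4	0.28	8	TRUE	FALSE
intake	chow	g/day	H	16.8	2.2	8	FALSE	FALSE
intake	chow	g/day	HO	11.5	2.9	8	FALSE	FALSE
intake	chow	g/day	FHO	14.0	0.5	8	FALSE	FALSE
intake	water	mL/day	H	25.2	0.2	8	FALSE	FALSE
intake	water	mL/day	HO	24.6	3.0	8	FALSE	FALSE
intake	water	mL/day	FHO	82.9	1.4	8	TRUE	TRUE
intake	caloric_intake	kcal/day	H	48.7	6.0	8	FALSE	FALSE
intake	caloric_intake	kcal/day	HO	33.3	8.5	8	FALSE	FALSE
intake	caloric_intake	kcal/day	FHO	73.7	0.8	8	TRUE	TRUE
hemodynamic	sap	mmHg	H	174	5	8	FALSE	FALSE
hemodynamic	sap	mmHg	HO	183	6	8	FALSE	FALSE
hemodynamic	sap	mmHg	FHO	206	4	8	TRUE	TRUE
hemodynamic	dap	mmHg	H	121	7	8	FALSE	FALSE
hemodynamic	dap	mmHg	HO	144	5	8	TRUE	FALSE
hemodynamic	dap	mmHg	FHO	153	2	8	TRUE	TRUE
hemodynamic	map	mmHg	H	146	6	8	FALSE	FALSE
hemodynamic	map	mmHg	HO	164	5	8	TRUE	FALSE
hemodynamic	map	mmHg	FHO	174	4	8	TRUE	TRUE
hemodynamic	hr	bpm	H	352	13	8	FALSE	FALSE
hemodynamic	hr	bpm	HO	348	16	8	FALSE	FALSE
hemodynamic	hr	bpm	FHO	403	12	8	TRUE	TRUE
hrv	hrv_sd	ms	H	6.62	0.61	8	FALSE	FALSE
hrv	hrv_sd	ms	HO	8.63	1.00	8	FALSE	FALSE
hrv	hrv_sd	ms	FHO	5.43	0.96	8	FALSE	TRUE
hrv	hrv_var	ms2	H	53.97	7.98	8	FALSE	FALSE
hrv	hrv_var	ms2	HO	63.64	10.34	8	FALSE	FALSE
hrv	hrv_var	ms2	FHO	30.84	6.81	8	FALSE	TRUE
hrv	hrv_lf	ms2	H	3.18	0.55	8	FALSE	FALSE
hrv	hrv_lf	ms2	HO	3.94	0.97	8	FALSE	FALSE
hrv	hrv_lf	ms2	FHO	0.90	0.12	8	FALSE	TRUE
hrv	hrv_hf	ms2	H	5.97	1.41	8	FALSE	FALSE
hrv	hrv_hf	ms2	HO	9.22	2.03	8	FALSE	FALSE
hrv	hrv_hf	ms2	FHO	2.77	0.18	8	FALSE	FALSE
bpv	bpv_var	mmHg2	H	31.08	2.66	8	FALSE	FALSE
bpv	bpv_var	mmHg2	HO	51.94	6.94	8	TRUE	FALSE
bpv	bpv_var	mmHg2	FHO	77.79	11.87	8	TRUE	TRUE
bpv	bpv_lf	mmHg2	H	5.06	0.91	8	FALSE	FALSE
bpv	bpv_lf	mmHg2	HO	5.07	0.52	8	FALSE	FALSE
bpv	bpv_lf	mmHg2	FHO	10.62	2.33	8	TRUE	TRUE
inflammation	tnf_alpha	pg/mg protein	H	32.9	7.5	8	FALSE	FALSE
inflammation	tnf_alpha	pg/mg protein	HO	31.7	8.6	8	FALSE	FALSE
inflammation	tnf_alpha	pg/mg protein	FHO	65.8	9.9	8	TRUE	TRUE
inflammation	il6	pg/mg protein	H	379	27	8	FALSE	FALSE
inflammation	il6	pg/mg protein	HO	368	26	8	FALSE	FALSE
inflammation	il6	pg/mg protein	FHO	401	35	8	FALSE	FALSE
inflammation	il10	pg/mg protein	H	37.1	9.0	8	FALSE	FALSE
inflammation	il10	pg/mg protein	HO	29.6	3.4	8	FALSE	FALSE
inflammation	il10	pg/mg protein	FHO	16.2	2.5	8	TRUE	FALSE
oxidative	tbars	umol/mg protein	H	4.95	0.89	8	FALSE	FALSE
oxidative	tbars	umol/mg protein	HO	8.27	0.98	8	TRUE	FALSE
oxidative	tbars	umol/mg protein	FHO	12.03	0.93	8	TRUE	TRUE
oxidative	chemiluminescence	cps/mg protein	H	6661	566	8	FALSE	FALSE
oxidative	chemiluminescence	cps/mg protein	HO	6514	547	8	FALSE	FALSE
oxidative	chemiluminescence	cps/mg protein	FHO	15043	1333	8	TRUE	TRUE
oxidative	catalase	nmol/mg protein	H	0.29	0.04	8	FALSE	FALSE
oxidative	catalase	nmol/mg protein	HO	0.47	0.05	8	TRUE	FALSE
oxidative	catalase	nmol/mg protein	FHO	0.63	0.05	8	TRUE	TRUE
oxidative	sod	USOD/mg protein	H	11.47	0.37	8	FALSE	FALSE
oxidative	sod	USOD/mg protein	HO	11.17	0.41	8	FALSE	FALSE
oxidative	sod	USOD/mg protein	FHO	13.05	0.86	8	FALSE	FALSE
oxidative	gpx	nmol/min/mg protein	H	54.78	3.10	8	FALSE	FALSE
oxidative	gpx	nmol/min/mg protein	HO	38.55	1.67	8	TRUE	FALSE
oxidative	gpx	nmol/min/mg protein	FHO	63.39	5.52	8	FALSE	TRUE
oxidative	gsh_gssg	ratio	H	11.07	0.7	8	FALSE	FALSE
oxidative	gsh_gssg	ratio	HO	13.00	1.4	8	FALSE	FALSE
oxidative	gsh_gssg	ratio	FHO	8.94	0.8	8	FALSE	TRUE
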