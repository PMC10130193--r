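pt_code,pt_name
10000358,Accelerated hypertension
10005732,Blood pressure ambulatory increased
10005739,Blood pressure diastolic increased
10051128,Blood pressure inadequately controlled
10005750,Blood pressure increased
10063926,Blood pressure management
10053355,Blood pressure orthostatic increased
10005760,Blood pressure systolic increased
10081751,Catecholamine crisis
10063067,Dialysis induced hypertension
10012758,Diastolic hypertension
10014129,Eclampsia
10057615,Endocrine hypertension
10015488,Essential hypertension
10070538,Gestational hypertension
10049058,HELLP syndrome
10020571,Hyperaldosteronism
10020772,Hypertension
10049781,Hypertension neonatal
10059238,Hypertensive angiopathy
10020801,Hypertensive cardiomegaly
10058222,Hypertensive cardiomyopathy
10077000,Hypertensive cerebrovascular disease
10020802,Hypertensive crisis
10058179,Hypertensive emergency
10020803,Hypertensive encephalopathy
10079496,Hypertensive end-organ damage
10020823,Hypertensive heart disease
10055171,Hypertensive nephropathy
10058181,Hypertensive urgency
10049079,Labile hypertension
10025600,Malignant hypertension
10025603,Malignant hypertensive heart disease
10026674,Malignant renal hypertension
10026924,Maternal hypertension affecting foetus
10026985,Mean arterial pressure increased
10052066,Metabolic syndrome
10067598,Neurogenic hypertension
10065508,Orthostatic hypertension
10076704,Page kidney
10050631,Postoperative hypertension
10036485,Pre-eclampsia
10065918,Prehypertension
10062886,Procedural hypertension
10038464,Renal hypertension
10074864,Renal sympathetic nerve ablation
10038562,Renovascular hypertension
10038926,Retinopathy hypertensive
10039808,Secondary aldosteronism
10039834,Secondary hypertension
10084825,Superimposed pre-eclampsia
10078932,Supine hypertension
10042957,Systolic hypertension
10048007,Withdrawal hypertension
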