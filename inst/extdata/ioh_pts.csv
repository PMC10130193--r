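pt_code,pt_name
10008786,Choroidal haemorrhage
10010719,Conjunctival haemorrhage
10015926,Eye haemorrhage
10020923,Hyphaema
10030919,Optic disc haemorrhage
10038867,Retinal haemorrhage
10047655,Vitreous haemorrhage
10050508,Scleral haemorrhage
10051558,Corneal bleeding
10057417,Ciliary body haemorrhage
10057418,Iris haemorrhage
10068642,Choroidal haematoma
10071934,Intraocular haematoma
10071935,Subretinal haematoma
10071936,Vitreous haematoma
10079891,Eye haematoma
10085163,Scleral haematoma
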