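pfam_acc	role	description
PF01618	motor_pentamer	MotA/ExbB/TolQ proton channel (pentameric motor subunit)
PF02472	motor_dimer	MotB/ExbD/TolR peptidoglycan-binding motor subunit (dimeric)
PF06519	transducer	TolA-TonB force transducer
PF03544	transducer	TonB C-terminal domain (shared TolA/TonB CTD fold)
PF13103	transducer	TolA-TonB force transducer (divergent family)
PF16031	transducer	TonB polyproline region
PF07676	tolB_propeller	TolB six-bladed beta-propeller (WD40-like)
PF04052	tolB_nterm	TolB N-terminal Rossmann-fold domain
PF00691	pal	OmpA-like peptidoglycan-binding domain (Pal)
PF16331	cpoB_tpr	TPR repeat (CpoB)
PF13432	cpoB_tpr	TPR repeat (CpoB)
PF13174	cpoB_tpr	TPR repeat (CpoB)
PF03061	ybgC	Acyl-CoA thioesterase (YbgC)
PF00593	tbdt_barrel	TonB-dependent receptor beta-barrel
PF07715	tbdt_plug	TonB-dependent receptor plug domain
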