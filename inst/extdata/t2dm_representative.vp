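id: t2dm_rep
name: Representative T2DM patient
phenotypes: t2dm
note: calibrated to FPG ~10.1 mM, OGTT AUC ~29.9 mM.h, FPI ~90 pM
override: SI_hepatic	0.093100000000000002
override: SI_peripheral	0.74639999999999995
override: B_func	0.45810000000000001
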