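section	parameter	label	control	category	row	column
Meals	meal_kcal	Calories per meal	text	DOSE	1	1
Meals	meal_frac_carb	Carbohydrate fraction	text	FRACTION	1	2
Meals	meal_time_1	Breakfast time	text	TIME	2	1
Drugs	ogtt_glucose	OGTT load	text	DOSE	1	1
Drugs	ogtt_auc_window	AUC window	dropdown	TIME	1	2
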