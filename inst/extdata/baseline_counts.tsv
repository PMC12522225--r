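covariate	level	train	validation	test
sex	Male	149	69	97
sex	Female	91	34	51
smoking	Smoker	55	34	36
smoking	Non-Smoker	160	62	98
smoking	Unknown	25	7	14
drinking	Drinker	63	33	41
drinking	Non-Drinker	151	63	92
drinking	Unknown	26	7	15
group	ESPL	50	15	26
group	StageI-II	62	38	47
group	StageIII-IV	30	8	14
group	Health	15	7	7
group	Benign	83	35	54
subgroup	LGIN	23	8	15
subgroup	HGIN	27	7	11
subgroup	StageI	51	35	38
subgroup	StageII	11	3	9
subgroup	StageIII	21	6	8
subgroup	StageIV	9	2	6
subgroup	Health	15	7	7
subgroup	Benign	83	35	54
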