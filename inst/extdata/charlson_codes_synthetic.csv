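code,category
C041,myocardial_infarction
C042,congestive_heart_failure
C043,peripheral_vascular_disease
C044,cerebrovascular_disease
C045,dementia
C046,chronic_pulmonary_disease
C047,rheumatologic_disease
C048,peptic_ulcer_disease
C049,mild_liver_disease
C050,diabetes
C051,diabetes_with_complications
C052,hemiplegia_paraplegia
C053,renal_disease
C054,any_malignancy
C055,moderate_severe_liver_disease
C056,metastatic_solid_tumor
C057,aids
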