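table,variable,category,n_active,n_placebo
age_cee_alone,age,65-69,123,128
age_cee_alone,age,70-74,93,89
age_cee_alone,age,75+,38,39
age_cee_mpa,age,65-69,220,225
age_cee_mpa,age,70-74,147,150
age_cee_mpa,age,75+,53,60
age_ht,age,65-69,343,353
age_ht,age,70-74,240,239
age_ht,age,75+,91,99
smoking_cee_alone,smoking,never,147,142
smoking_cee_alone,smoking,former,95,98
smoking_cee_alone,smoking,current,9,15
smoking_cee_mpa,smoking,never,248,247
smoking_cee_mpa,smoking,former,152,168
smoking_cee_mpa,smoking,current,18,15
prior_cvd_cee_alone,prior_cvd,none,233,233
prior_cvd_cee_alone,prior_cvd,stroke,3,4
prior_cvd_cee_alone,prior_cvd,other_cvd,18,19
prior_ht_cee_alone,prior_ht,no,129,124
prior_ht_cee_alone,prior_ht,yes,125,132
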