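parameter_id,model_label,form,a,b,c,n,m,cap_age_days,min_age_days
sc_thickness,sc_model_1,polynomial,2.401e-7,-99.43,101.4,2.000,2.071e-3,1510,1
sc_thickness,sc_model_2,polynomial,2.662e-7,0,0.724,1.878,0,1604,0
ed_thickness,epidermis,hill,0.366,18.702,0.634,5.363,NA,NA,0
de_thickness,dermis,sigmoid,1.093,8974,0.407,NA,NA,9883,0
sc_hydration,hydration,polynomial,-0.344,-17.585,18.530,0.245,-0.0171,1182,1
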