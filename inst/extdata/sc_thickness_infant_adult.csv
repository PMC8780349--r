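site,infant_mean_um,infant_sd_um,adult_mean_um,adult_sd_um,age_range,reference
lower thigh,7.3,1.1,10.5,2.1,3 months - 2 years,Stamatas et al.
upper inner arm,5.3,1.4,7.9,1.8,3 months - 2 years,Liu et al.
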