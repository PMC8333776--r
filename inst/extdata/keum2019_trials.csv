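study,rr,ci_lower,ci_upper,n,dose
Trivedi 2003,0.86,0.61,1.20,2686,100 000 IU per 4 months
Wactawski-Wende 2006,0.89,0.77,1.03,36282,400 IU per day
Avenell 2012,0.85,0.68,1.06,5292,800 IU per day
Scragg 2018,0.99,0.60,1.64,5110,100 000 IU per month after bolus
Manson 2019,0.83,0.67,1.02,25871,2000 IU per day
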