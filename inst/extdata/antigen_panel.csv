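# Median sensitivities/specificities (with 95% CIs, percent) of three
# widely used rapid SARS-CoV-2 antigen tests in symptomatic patients,
# as reported by a published systematic review of antigen test accuracy.
name,tpr,tpr_lo,tpr_hi,tnr,tnr_lo,tnr_hi
abbott_panbio,74.8,67.6,80.8,99.7,99.6,99.8
innova_ag,68.1,47.2,83.6,99.0,98.5,99.3
siemens_clinitest,68.7,48.0,83.8,100,98.0,100
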