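# Antibody assays used (AND-combined: every Abbott-positive sample was
# confirmed by the Euroimmun ELISA) in the Norrbotten County, Sweden,
# 2020 seroprevalence study. Values in percent with 95% CIs where the
# validation studies reported them.
name,tpr,tpr_lo,tpr_hi,tnr,tnr_lo,tnr_hi
abbott_igg,83.1,75.4,100,100,,
euroimmun_elisa,91.1,80.7,96.1,100,96.5,100
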