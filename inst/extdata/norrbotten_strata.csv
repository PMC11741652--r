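# Measured (apparent) seroprevalence by age stratum from the Norrbotten
# County, Sweden, 2020 serosurvey (AND-combined antibody protocol),
# plus cumulative fatality/hospitalization counts and the county
# population used for severity ratios. Proportions, not percent.
stratum,measured,measured_lo,measured_hi,fatalities,hospitalizations,population
20-29,0.066,0.018,0.159,NA,NA,NA
30-64,0.007,0.001,0.027,NA,NA,NA
65-80,0.021,0.003,0.073,NA,NA,NA
all,0.019,0.008,0.037,59,242,249614
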