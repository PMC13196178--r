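"age","sbp","log_creatinine","ethnicity"
24.1,152,4.356,"groupA"
31.9,122,4.874,"groupB"
28.3,135,4.113,"groupA"
27.3,148,3.981,"groupA"
34.9,123,4.197,"groupB"
28.8,141,4.27,"groupB"
34,134,4.474,"groupB"
26.3,160,4.548,"groupB"
28.7,117,4.693,"groupB"
29.1,138,4.354,"groupB"
32.6,153,4.811,"groupB"
34.4,130,4.127,"groupA"
32.9,142,4.089,"groupA"
29,138,4.222,"groupB"
33.3,146,4.877,"groupA"
28.7,113,4.235,"groupA"
27.1,169,3.957,"groupA"
37,107,4.535,"groupA"
32.5,128,3.955,"groupA"
26.5,123,4.371,"groupB"
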