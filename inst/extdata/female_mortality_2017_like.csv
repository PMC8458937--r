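# All-cause annual death probability q(x), women of all ethnicities.
# Synthetic emulation of a US period life table (circa 2017): approximate
# transcription of the single-year q(x) magnitudes for ages 55-75. Values are
# strictly increasing in age, as in any period life table for this age span.
# Not a verbatim copy of any NVSS release.
age,annual_probability
55,0.005093
56,0.005486
57,0.005884
58,0.006282
59,0.006711
60,0.007202
61,0.007756
62,0.008353
63,0.008969
64,0.009611
65,0.010319
66,0.011129
67,0.012033
68,0.013025
69,0.014126
70,0.015372
71,0.016790
72,0.018380
73,0.020119
74,0.021978
75,0.023938
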