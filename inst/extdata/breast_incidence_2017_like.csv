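# Age-specific invasive female breast cancer incidence, annual probability per woman.
# Synthetic emulation of SEER-style age-adjusted incidence rates (circa 2017, all
# ethnicities): approximate transcription of published 5-year age-group magnitudes
# (per 100,000: 55-59 ~265, 60-64 ~347, 65-69 ~421, 70-74 ~464, 75-79 ~463),
# linearly interpolated to single years of age. Not a verbatim copy of any
# registry release; intended to reproduce the level and age-trend only.
age,annual_probability
55,0.002316
56,0.002481
57,0.002646
58,0.002811
59,0.002976
60,0.003141
61,0.003306
62,0.003471
63,0.003619
64,0.003768
65,0.003916
66,0.004065
67,0.004213
68,0.004299
69,0.004385
70,0.004471
71,0.004557
72,0.004643
73,0.004641
74,0.004638
75,0.004636
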