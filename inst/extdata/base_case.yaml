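pretest_probability: 0.016500000000000001
start_age: 55.0
screening_interval: 2
horizon: 20
discount_rate: 0.029999999999999999
wtp: 100000.0
sens_xm: 0.41199999999999998
spec_xm: 0.90000000000000002
sens_mrm: 0.95199999999999996
spec_mrm_round1: 0.92000000000000004
spec_mrm_later: 0.96999999999999997
biopsy_rate_fp_round1: 0.67200000000000004
biopsy_rate_fp_later: 0.80200000000000005
cost_xm: 101.52
cost_mrm: 314.0
cost_biopsy: 1536.0
cost_tx_small: 60637.0
cost_tx_large: 82121.0
cost_tx_advanced: 129387.0
qol_healthy: 1.0
qol_small: 0.87
qol_large: 0.73999999999999999
qol_advanced: 0.62
qol_post_simple: 0.98999999999999999
qol_post_intensive: 0.94999999999999996
qol_fp_decrement: 0.01
death_risk_undetected_cum: 0.10000000000000001
undetected_risk_span: 10.0
death_small_annual: 0.0011000000000000001
death_large_annual: 0.0077999999999999996
death_advanced_annual: 0.018100000000000002
p_r0_small: 1.0
p_r0_large: 0.90000000000000002
p_nplus_small: 0.0
p_nplus_large: 0.40000000000000002
p_small_if_detected_within_interval: 1.0
interval_detection: 0.84999999999999998
advanced_dwell_threshold: 3
excess_risk_duration: 5
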