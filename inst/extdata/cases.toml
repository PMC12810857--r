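# Case-study fixtures: observed strategy means and the parameter overrides
# reported for each supervision scenario. Fields not listed for a case fall
# back to the baseline parameter set.

[saudi_tb]
description = "Tuberculosis treatment adherence supervision, Saudi Arabia (community mobile outreach teams)"
observed_delta = 0.795
observed_eta = 0.825
observed_zeta = 0.733
mu = 0.8
vm2 = 20
theta = 0.6

[guangdong_covid]
description = "COVID-19 vaccination compliance supervision, Guangdong, China (mobile teams + public reporting platform)"
observed_delta = 0.72
observed_eta = 0.91
observed_zeta = 0.85
mu = 0.83
vm2 = 18
theta = 0.7

[vietnam_antibiotics]
description = "Antibiotic prescription compliance supervision, rural Vietnamese clinics (stewardship-trained mobile teams + public hotline)"
observed_delta = 0.65
observed_eta = 0.76
observed_zeta = 0.70
mu = 0.78
vm2 = 22
theta = 0.65
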