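scholarship: 11865.6
pcf_full: 7130.0
pcf_pmmb: 4000.0
pcf_dif: 3130.0
ref_central: 6500.0
ref_decentralized: 6000.0
n_decentralized: 7
rent: 2000.0
food: 600.0
physician_wage_monthly: 20236.249599999999
sensitivity_fraction: 0.3
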