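bands:
- 412.0
- 443.0
- 490.0
- 510.0
- 520.0
- 550.0
- 555.0
- 560.0
- 620.0
- 665.0
- 670.0
- 682.0
aw:
  '412': 0.00455
  '443': 0.00707
  '490': 0.015
  '510': 0.0325
  '520': 0.0417
  '550': 0.0565
  '555': 0.0596
  '560': 0.0619
  '620': 0.2755
  '665': 0.4295
  '670': 0.439
  '682': 0.47
bbw_ref: 0.00144
bbw_slope: -4.32
cdom_frac: 0.2
cdom_slope: 0.014
bbp_ref: 0.0012
bbp_exp: 0.62
bbp_slope: 1.0
f_factor: 0.089
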