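Ga: -1.51
Gb: -1.25
Gc: 14.95
Gd: 0.25
Ha: 0.29
Hb: 3.05
Hc: 16.24
Hd: 0.56
Ja: 0.37
Jb: 1.13
Jc: 14.89
Jd: 0.569
Ka: 0.503
Kb: 1.33
Kc: 17.31
Kd: 0.258
alpha: 0.1
beta: 32.5
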