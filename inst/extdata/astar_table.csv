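wavelength,group,a_star,sd
412,pico,0.124,0.054
443,pico,0.183,0.043
490,pico,0.118,0.025
510,pico,0.067,0.02
520,pico,0.053,0.016
550,pico,0.028,0.01
555,pico,0.023,0.009
560,pico,0.018,0.008
620,pico,0.016,0.007
665,pico,0.037,0.01
670,pico,0.052,0.013
682,pico,0.054,0.013
412,nano,0.052,0.031
443,nano,0.039,0.027
490,nano,0.022,0.018
510,nano,0.018,0.015
520,nano,0.016,0.013
550,nano,0.011,0.008
555,nano,0.011,0.007
560,nano,0.011,0.006
620,nano,0.007,0.005
665,nano,0.009,0.008
670,nano,0.011,0.01
682,nano,0.012,0.009
412,dino,0.039,0.014
443,dino,0.041,0.016
490,dino,0.035,0.008
510,dino,0.026,0.005
520,dino,0.022,0.004
550,dino,0.013,0.002
555,dino,0.012,0.002
560,dino,0.01,0.002
620,dino,0.008,0.001
665,dino,0.01,0.006
670,dino,0.011,0.008
682,dino,0.009,0.008
412,diatom,0.011,0.004
443,diatom,0.016,0.005
490,diatom,0.009,0.003
510,diatom,0.008,0.003
520,diatom,0.007,0.002
550,diatom,0.004,0.001
555,diatom,0.003,0.001
560,diatom,0.003,0.001
620,diatom,0.004,0.001
665,diatom,0.013,0.002
670,diatom,0.015,0.002
682,diatom,0.012,0.002
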