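seed: 1
theta_CL: 22.0
theta_V1: 162.0
theta_Q: 69.40000000000000568
theta_V2: 87.90000000000000568
omega2_CL: 0.02948986782678737
omega2_V1: 0.03620077310581595
omega2_V2: 0.13956105263294821
pi2_CL: 0.02052393571815193
pi2_V2: 0.0423542600016875
sigma_add: 0.021
sigma2_prop: 0.0169
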