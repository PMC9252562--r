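beta: 0.01324
kappa: 0.2
gamma: 0.111111111111111
rho: 0.25
alpha: 0.4
sigma: 0.5
epsilon: 0.7
b: 48.0
nu1: 0.1
nu2: 0.05
tau1: 14
tau2: 14
delta: 0.99986
phi: 1.0
p: 0.66
symptomatic_utility: zero
terminal_value: 0.0
i0: 0.0001
t_max: 1000
stop_tol: 1.0e-07
seed_split: proportional
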