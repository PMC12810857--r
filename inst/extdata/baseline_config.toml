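# Baseline run configuration: Saudi TB supervision scenario parameters.

[parameters]
ip1 = 30
ip2 = 20
mu = 0.8
bp = 15
im1 = 40
cm1 = 30
im2 = 20
cm2 = 15
theta = 0.6
vm2 = 20
bm = 70
cc = 15
ig1 = 30
w = 25
cg1 = 15
ig2 = 20
bg = 25

[run]
init = [0.5, 0.5, 0.5]
horizon = 200
rel_tol = 1e-8
abs_tol = 1e-10
seed = 0
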