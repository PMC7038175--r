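out: hof-out
alpha: 10.0
gamma: 100.0
order: 4
window: 5
levels: 5
iterations: 50
warps: 3
baseline: no
epsilon: 1.0
noise-sigma: 0.0
noise-preset: no
kind: beating_ellipsoid
shape: '32,32,32'
amplitude: .na.real
phases: 10
seed: 1
format: auto
quiet: no
command: frobnicate
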