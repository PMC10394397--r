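# Example block-RAR design: 2 experimental arms, burn-in of 2 per arm,
# two adaptive blocks of 4 experimental + 3 control patients.
# `seed` fixes the pre-specified uniform auxiliary design.
K: 2
burn_in_per_arm: 2
control_burn_in: 2
aux_block_totals: [4, 4]
control_block_sizes: [3, 3]
alpha: 0.05
sigma2: 1
scheme: bar
gamma: 0.5
seed: 11
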