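# single-source experiment at the canonical contextual-cueing scale
n_participants: 14
k_per_condition: 48
k_direct_per_condition: 12
delta: 50
sigma_eps: 400
sigma_effect: 120
rt_model: lognormal
source_model: single_source
seed: 42
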