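alpha: 14933.1
beta: 120.539
lambda: 0.37816
n_total: 40
m: 20
censor_time: 205
seed: 101
note: synthetic sample simulated from the recorded parameters
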