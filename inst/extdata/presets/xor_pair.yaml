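# Outcome driven purely by the interaction (exclusive or) of two binary
# factors; marginal associations are null. Four extra null noise factors.
generator: xor_pair
n_subjects: 400
effect: 0.25
n_noise: 4
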