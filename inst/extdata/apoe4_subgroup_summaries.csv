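label,md,ci_lower,ci_upper,se,n_a,n_b
TRAILBLAZER-ALZ2,-0.41,,,0.30,123,97
Clarity,0.28,,,0.31,132,136
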