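center_id,acceptance_propensity,screen_propensity
1,0.4,0.8
2,0.2,0.6
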