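offer_id,center_id,patient_id,donor_id,marginal,seen,accepted
1,1,1,1,1,1,0
2,1,2,1,1,1,1
3,2,3,2,0,0,0
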