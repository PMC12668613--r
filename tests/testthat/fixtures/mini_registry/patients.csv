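patient_id,center_id,age_at_listing,diabetes,blood_type,previous_transplant,cpra,bmi,albumin,sdi,waiting_time_elapsed,active,chf,ashd,tobacco,cancer,outcome_type,outcome_time,donor_id,donor_quality,post_tx_time,post_tx_event,graft_failed,relisted
1,1,57.5,1,O,0,0,31.2,3.8,64,4.2,1,0,0,0,0,death_or_delisting,1.25,NA,NA,NA,NA,NA,NA
2,1,44,0,A,1,99.7,26.1,4.1,35,0.5,1,0,0,0,0,transplant,3.5,2,0.81,6.2,1,0,NA
3,2,68.3,1,B,0,42,29,3.5,58,2.9,0,1,0,1,0,censored,10,NA,NA,NA,NA,NA,NA
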