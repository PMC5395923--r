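patient_id,finding_id,rater1,rater2
P01,F001,1,1
P01,F002,1,0
P01,F003,0,1
P02,F001,1,1
P02,F002,1,1
P03,F001,0,1
P04,F001,1,1
P04,F002,1,0
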