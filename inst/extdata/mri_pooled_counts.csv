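patient_id,b,c,d
pooled,19,57,173
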