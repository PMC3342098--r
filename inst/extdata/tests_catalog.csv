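test_id,turnaround_days
cxr,1
sputum_smear3,3
pleural_tap,1
ultrasound,1
antibiotic_trial,5
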