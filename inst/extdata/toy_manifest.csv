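sample_id,role,compartment,group,age_weeks,qc_group
S1,study,serum,SPF,2,
S2,study,serum,LPS,2,
S3,study,brain,SPF,2,
S4,study,brain,LPS,2,
B1,solvent_blank,none,none,,
M1,method_blank,none,none,,
Q1,pooled_qc,none,none,,QC1
Q2,pooled_qc,none,none,,QC1
Q3,pooled_qc,none,none,,QC1
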