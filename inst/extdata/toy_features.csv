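feature_id,mz,rt_min,putative_id,contaminant_flag,S1,S2,S3,S4,B1,M1,Q1,Q2,Q3
F01,408.2881,3.10,cholic acid (internal standard),FALSE,2,4,2,2,2,2,2,2,2
F02,150.1000,0.50,solvent carryover peak,FALSE,10,10,10,10,1500000,0,10,10,10
F03,210.1200,1.20,compound alpha,FALSE,10,20,10,10,1000000,0,10,10,10
F04,305.2000,2.40,compound beta,FALSE,0.5,0.5,0.5,0.5,0,2,1,1,1
F05,120.0800,0.80,compound gamma,FALSE,10,10,10,10,0,0,2,2.4,1.6
F06,413.2662,4.00,polyethylene glycol oligomer,TRUE,10,10,10,10,0,0,2,2,2
F07,520.3400,5.10,compound delta,FALSE,10,12,8,9,0,0,2,2,2
F08,260.1600,1.90,compound epsilon,FALSE,6,6,6,6,0,0,4,4,4
F09,180.1000,0.60,compound zeta,FALSE,0,0,0,0,0,0.5,0,0,0
F10,441.2975,4.20,polypropylene glycol oligomer,TRUE,10,10,10,10,1200000,0,2,2,2
F11,330.2100,2.80,compound eta,FALSE,100,90,110,100,0,0,30,30,30
F12,495.3300,4.80,compound theta,FALSE,50,50,50,50,1000,0,10,10,10
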