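model,term,estimate,se,ci_low,ci_high
rate,age_difference,0.002,0.014,-0.026,0.030
rate,kinship_non_kin,-0.608,0.306,-1.222,-0.012
rate,rank_distance,-0.073,0.048,-0.167,0.026
rate,relative_rank_subordinate,0.587,0.214,0.148,1.045
rate,friendship,0.405,0.045,0.317,0.493
rate,groom_received,1.229,0.038,0.496,1.959
rate,co_provisioning,0.140,0.141,-0.134,0.415
rate,aggression_received,2.156,0.488,1.210,3.117
rate,season_2,-0.363,0.152,-0.658,-0.063
time,age_difference,0.004,0.019,-0.034,0.040
time,kinship_non_kin,-0.645,0.402,-1.451,0.140
time,rank_distance,-0.102,0.064,-0.226,0.028
time,relative_rank_subordinate,0.929,0.292,0.330,1.554
time,friendship,0.531,0.056,0.421,0.640
time,groom_received,0.159,0.115,-0.063,0.383
time,co_provisioning,0.213,0.187,-0.149,0.577
time,aggression_received,2.775,0.644,1.520,4.041
time,season_2,-0.686,0.203,-1.079,-0.289
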