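id,label,base,low,high,family,role
im_noncr_induction,"Imatinib: non-CR after induction therapy",1,NA,NA,beta,transition
im_noncr_intensive,"Imatinib: non-CR after intensive chemotherapy",0.5,NA,NA,beta,transition
im_relapse_maint,"Imatinib: relapse in maintenance therapy",0.1000,0.0415,0.1729,beta,transition
im_death_cr_maint,"Imatinib: death of CR patients in maintenance therapy",0.0879,0.0364,0.1365,beta,transition
da_noncr_induction,"Dasatinib: non-CR after induction therapy",0.833,NA,NA,beta,transition
da_cr_stays_cr_intensive,"Dasatinib: CR of CR patients in intensive chemotherapy",1,NA,NA,beta,transition
da_cr_of_noncr_intensive,"Dasatinib: CR of non-CR patients in intensive chemotherapy",0.875,NA,NA,beta,transition
da_relapse_maint,"Dasatinib: relapse in maintenance therapy",0.0537,0.0107,0.1035,beta,transition
da_death_cr_maint,"Dasatinib: death of CR patients in maintenance therapy",0.0304,0.0099,0.0504,beta,transition
death_noncr_maint,"Death of non-CR patients in maintenance therapy",0.6,0.54,0.66,beta,transition
hsct_rate,"Transplantation in non-CR patients",0.1,0.09,0.11,beta,transition
hsct_success,"Success in transplantation",0.4,0.3,0.5,beta,transition
hsct_relapse,"Relapse after transplantation",0.0582,0.0354,0.0806,beta,transition
hsct_death_cr,"Death in CR patients after transplantation",0.23,0.21,0.25,beta,transition
hsct_death_noncr,"Death in non-CR/relapse patients after transplantation",0.57,0.49,0.64,beta,transition
im_drug_cost,"Imatinib: drug cost per year",104857.2,83885.76,125828.64,gamma,cost
im_other_induction,"Imatinib: other costs in induction therapy",71019.18,10168.61,170406.88,gamma,cost
im_other_intensive,"Imatinib: other costs in intensive chemotherapy",266871.23,120615.16,398733.09,gamma,cost
da_drug_cost,"Dasatinib: drug cost per year",51100,40880,61320,gamma,cost
da_other_induction,"Dasatinib: other costs in induction therapy",91338.95,26639.48,176128.92,gamma,cost
da_other_intensive,"Dasatinib: other costs in intensive chemotherapy",208152.13,141714.97,274986.24,gamma,cost
cost_cr_maint,"Other costs for maintenance in CR state",57500,46000,69000,gamma,cost
cost_noncr_maint,"Maintenance in non-CR state",375953.99,244489.6,531322.71,gamma,cost
cost_hsct,"Transplantation (one-off)",250000,200000,300000,gamma,cost
cost_hsct_cr_maint,"Maintenance in CR state after transplantation",399953.99,268489.6,555322.71,gamma,cost
cost_hsct_fail,"non-CR/relapse after transplantation",1000000,800000,1200000,gamma,cost
im_dur_induction,"Imatinib: induction therapy duration (years)",0.0795,0.0795,0.0795,fixed,duration
im_dur_intensive,"Imatinib: intensive chemotherapy duration (years)",0.8164,0.8164,0.8164,fixed,duration
da_dur_induction,"Dasatinib: induction therapy duration (years)",0.0849,0.0849,0.0849,fixed,duration
da_dur_intensive,"Dasatinib: intensive chemotherapy duration (years)",0.6822,0.6822,0.6822,fixed,duration
u_cr,"Utility: CR",0.88,0.82,0.93,beta,utility
u_noncr,"Utility: non-CR/relapse",0.76,0.7,0.82,beta,utility
u_hsct_cr_early,"Utility: CR after transplantation (first 5 years)",0.8,0.74,0.86,beta,utility
u_hsct_cr_late,"Utility: CR after transplantation (second 5 years)",0.86,0.8,0.91,beta,utility
u_hsct_fail,"Utility: non-CR/relapse after transplantation",0.73,0.67,0.79,beta,utility
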