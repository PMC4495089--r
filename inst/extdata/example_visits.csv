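visit_id,practice_group,sector,age,has_dld,has_supplementary_insurance,sick_leave,sick_leave_days,radiology,ct_scan,mri,lab_test,nursing,physiotherapy,specialist_referral
V1,CM,S1,40,FALSE,TRUE,FALSE,0,FALSE,FALSE,FALSE,TRUE,FALSE,FALSE,FALSE
V2,Ho,S2,10,TRUE,TRUE,TRUE,5,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE
V3,Mx,NUA,30,FALSE,FALSE,FALSE,0,FALSE,FALSE,FALSE,FALSE,FALSE,FALSE,TRUE
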