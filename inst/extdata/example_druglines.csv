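visit_id,unit_price,n_boxes,tier,dld_related,is_homeopathic,drug_class
V1,10.00,1,0.65,FALSE,FALSE,N02
V1,4.50,2,0.35,FALSE,FALSE,R01
V2,6.00,1,0.65,TRUE,FALSE,N05B
V2,3.00,1,0.00,FALSE,TRUE,OTHER
V3,0.20,1,0.35,FALSE,FALSE,OTHER
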