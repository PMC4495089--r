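# 2008 French statutory tariff parameters for GP micro-costing
consultation_tariff_sector1: 22.00
consultation_tariff_sector2: 32.00
contractual_base: 22.00
ss_consultation_share: 0.70
adult_lump_sum: 1.00
adult_age_threshold: 18
franchise_per_box: 0.25
drug_tiers: [0.00, 0.35, 0.65, 1.00]
child_franchise_exempt: false
lump_sum_mode: net_ss
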