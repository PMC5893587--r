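species,family,lw_a,lw_b,lw_source_tier,max_length_mm,iconic
big_snapper,snapper,2e-8,3,1,800,FALSE
small_snapper,snapper,2e-8,3,1,350,FALSE
mid_snapper,snapper,2e-8,3,1,550,FALSE
big_grouper,grouper,2e-8,3,1,900,FALSE
small_grouper,grouper,2e-8,3,1,300,FALSE
mid_grouper,grouper,2e-8,3,1,500,FALSE
big_emperor,emperor,2e-8,3,1,600,FALSE
small_emperor,emperor,2e-8,3,1,300,FALSE
mid_emperor,emperor,2e-8,3,1,450,FALSE
goatfish_sp,goatfish,2e-8,3,1,400,FALSE
giant_jack,jack,2e-8,3,1,1600,TRUE
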