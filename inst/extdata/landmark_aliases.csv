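canonical,alias
pubic_symphysis_center,pubic_symphysis_center
pubic_symphysis_center,pubic_symphysis
pubic_symphysis_center,symphysis
pubic_symphysis_center,symphysis_pubis
pubic_symphysis_center,ps
sacrum_center,sacrum_center
sacrum_center,sacrum
sacrum_center,sacral_center
sacrum_center,sc
ischial_tuberosity_L,ischial_tuberosity_l
ischial_tuberosity_L,ischial_tuberosity_left
ischial_tuberosity_L,left_ischial_tuberosity
ischial_tuberosity_L,it_l
ischial_tuberosity_L,lit
ischial_tuberosity_R,ischial_tuberosity_r
ischial_tuberosity_R,ischial_tuberosity_right
ischial_tuberosity_R,right_ischial_tuberosity
ischial_tuberosity_R,it_r
ischial_tuberosity_R,rit
ischial_spine_L,ischial_spine_l
ischial_spine_L,ischial_spine_left
ischial_spine_L,left_ischial_spine
ischial_spine_L,is_l
ischial_spine_L,lis
ischial_spine_R,ischial_spine_r
ischial_spine_R,ischial_spine_right
ischial_spine_R,right_ischial_spine
ischial_spine_R,is_r
ischial_spine_R,ris
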