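participant,timepoint,observer,vis_iam_right,comp_iam_right,vis_cochlea_right,comp_cochlea_right,vis_vestibule_right,comp_vestibule_right,vis_iam_left,comp_iam_left,vis_cochlea_left,comp_cochlea_left,vis_vestibule_left,comp_vestibule_left,printed_certainty,printed_side
A,pre_registration,1,1,1,3,1,3,1,1,2,0,0,1,1,none,
A,pre_registration,2,1,2,3,2,3,2,1,2,0,0,0,0,definite,left
A,post_registration,1,1,1,3,2,3,2,1,2,0,0,1,1,definite,left
A,post_registration,2,1,2,3,2,3,2,1,2,0,0,0,0,definite,left
B,pre_registration,1,2,2,2,1,2,1,2,3,1,1,1,1,none,
B,pre_registration,2,1,1,1,1,1,1,2,2,1,1,1,1,none,
B,post_registration,1,1,2,2,1,2,1,2,2,1,1,1,1,none,
B,post_registration,2,1,1,1,1,0,0,2,3,1,2,1,2,none,
C,pre_registration,1,1,3,1,3,1,3,1,3,1,1,0,0,possible,left
C,pre_registration,2,1,3,1,2,1,2,1,3,0,0,1,1,possible,left
C,post_registration,1,1,3,1,3,1,3,1,3,0,0,0,0,possible,left
C,post_registration,2,1,3,1,2,1,2,1,3,0,0,0,0,possible,left
D,pre_registration,1,1,1,1,1,1,1,1,1,0,0,0,0,none,
D,pre_registration,2,1,1,2,1,2,1,1,1,1,1,1,1,none,
D,post_registration,1,1,2,2,2,1,1,1,1,0,0,0,0,definite,left
D,post_registration,2,1,1,2,1,2,2,1,1,0,0,1,1,possible,left
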