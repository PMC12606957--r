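participant,observer,eh_mean,eh_sd,eh_median,eh_scaled,normal_mean,normal_sd,normal_median,normal_scaled,printed_ratio,printed_scaled_ratio
A,1,6.4,2.7,6.2,0.7,8.4,3.8,7.9,1.7,1.5,2.0
A,2,5.4,2.1,6.0,0.6,10.1,4.5,10.1,1.4,1.5,2.0
B,1,7.0,1.3,7.7,0.9,5.5,2.9,6.4,0.8,0.8,0.8
B,2,6.0,3.2,7.1,1.1,5.7,2.6,5.9,0.7,0.8,0.8
C,1,5.5,2.5,4.7,0.4,4.9,1.1,5.1,0.5,1.2,1.2
C,2,4.8,2.8,3.6,0.4,3.9,1.9,4.5,0.5,1.2,1.2
D,1,6.3,3.0,5.2,0.6,5.9,3.9,8.2,1.7,1.3,2.8
D,2,3.5,1.5,3.5,0.3,4.3,3.1,2.9,0.5,1.3,2.8
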