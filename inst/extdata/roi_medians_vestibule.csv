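participant,observer,eh_mean,eh_sd,eh_median,eh_scaled,normal_mean,normal_sd,normal_median,normal_scaled,printed_ratio,printed_scaled_ratio
A,1,6.3,3.3,5.7,0.6,9.1,4.8,10.3,1.3,2.1,2.9
A,2,4.6,1.1,4.6,0.4,9.5,5.0,11.7,1.6,2.1,2.9
B,1,6.3,2.4,7.1,0.8,5.6,2.7,5.9,0.8,0.8,0.7
B,2,9.5,5.0,9.7,1.3,6.0,2.3,7.0,0.8,0.8,0.7
C,1,4.4,2.3,3.2,0.3,6.0,3.3,7.9,0.7,1.9,1.9
C,2,4.1,1.7,3.3,0.4,5.2,2.4,4.3,0.5,1.9,1.9
D,1,6.5,4.4,6.9,0.8,5.6,3.0,5.1,1.1,1.1,2.2
D,2,4.6,3.0,4.3,0.4,5.8,3.7,7.7,1.4,1.1,2.2
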