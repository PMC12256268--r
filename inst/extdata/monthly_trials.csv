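trial,cycle,delta_on_s,delta_off_s
1,1,-0.01,-0.07
1,2,0.10,0.04
1,3,0.04,-0.02
1,4,0.01,-0.02
1,5,-0.02,-0.10
1,6,NA,NA
2,1,0.07,0.04
2,2,-0.01,-0.07
2,3,0.04,-0.02
2,4,0.01,-0.04
2,5,0.04,-0.02
2,6,0.10,0.04
3,1,0.08,0.00
3,2,-0.04,-0.14
3,3,0.03,-0.05
3,4,-0.04,-0.11
3,5,-0.01,-0.11
3,6,0.10,0.04
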