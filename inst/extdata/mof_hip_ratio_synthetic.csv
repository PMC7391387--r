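"sex","age_lo","age_hi","rho"
"male",40,45,5.38
"male",45,50,5.12
"male",50,55,4.88
"male",55,60,4.62
"male",60,65,4.38
"male",65,70,4.12
"male",70,75,3.88
"male",75,80,3.62
"male",80,85,3.38
"male",85,90,3.12
"male",90,NA,2.75
"female",40,45,7.8
"female",45,50,7.4
"female",50,55,7
"female",55,60,6.6
"female",60,65,6.2
"female",65,70,5.8
"female",70,75,5.4
"female",75,80,5
"female",80,85,4.6
"female",85,90,4.2
"female",90,NA,3.6
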