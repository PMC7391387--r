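"sex","age_lo","age_hi","count"
"male",40,45,7480
"male",45,50,6312
"male",50,55,5984
"male",55,60,4984
"male",60,65,3552
"male",65,70,1704
"male",70,75,1104
"male",75,80,912
"male",80,85,480
"male",85,90,216
"male",90,NA,56
"female",40,45,7760
"female",45,50,6768
"female",50,55,6632
"female",55,60,5536
"female",60,65,3968
"female",65,70,2064
"female",70,75,1344
"female",75,80,1208
"female",80,85,752
"female",85,90,400
"female",90,NA,168
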