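"sex","age_lo","age_hi","rate","units"
"male",40,45,0.00183331,"per_person_year"
"male",45,50,0.00287521,"per_person_year"
"male",50,55,0.00450922,"per_person_year"
"male",55,60,0.00707186,"per_person_year"
"male",60,65,0.0110909,"per_person_year"
"male",65,70,0.017394,"per_person_year"
"male",70,75,0.0272792,"per_person_year"
"male",75,80,0.0427823,"per_person_year"
"male",80,85,0.067096,"per_person_year"
"male",85,90,0.105227,"per_person_year"
"male",90,NA,0.20667,"per_person_year"
"female",40,45,0.00113369,"per_person_year"
"female",45,50,0.00182299,"per_person_year"
"female",50,55,0.00293139,"per_person_year"
"female",55,60,0.00471372,"per_person_year"
"female",60,65,0.00757973,"per_person_year"
"female",65,70,0.0121883,"per_person_year"
"female",70,75,0.019599,"per_person_year"
"female",75,80,0.0315154,"per_person_year"
"female",80,85,0.0506772,"per_person_year"
"female",85,90,0.0814897,"per_person_year"
"female",90,NA,0.166164,"per_person_year"
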