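naproxen was given for liver injury .|Drug,0,8;Disease,23,35|
metformin - induced liver injury .|Drug,0,9;Disease,20,32|1,2,ADE
the patient developed rhabdomyolysis after taking acetylsalicylic acid .|Disease,22,36;Drug,50,70|2,1,ADE
the patient developed skin rash after taking valproic acid .|Disease,22,31;Drug,45,58|2,1,ADE
the patient developed nephritis after taking fusidic acid .|Disease,22,31;Drug,45,57|2,1,ADE
fusidic acid was given for hypoglycemia .|Drug,0,12;Disease,27,39|
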