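naproxen was given for liver injury .
metformin - induced liver injury .
the patient developed rhabdomyolysis after taking acetylsalicylic acid .
the patient developed skin rash after taking valproic acid .
the patient developed nephritis after taking fusidic acid .
fusidic acid was given for hypoglycemia .
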