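T1	Drug 0 8	naproxen
T2	Disease 23 35	liver injury
T3	Drug 38 47	metformin
T4	Disease 58 70	liver injury
T5	Disease 95 109	rhabdomyolysis
T6	Drug 123 143	acetylsalicylic acid
T7	Disease 168 177	skin rash
T8	Drug 191 204	valproic acid
T9	Disease 229 238	nephritis
T10	Drug 252 264	fusidic acid
T11	Drug 267 279	fusidic acid
T12	Disease 294 306	hypoglycemia
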