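R1	ADE Arg1:T3 Arg2:T4
R2	ADE Arg1:T6 Arg2:T5
R3	ADE Arg1:T8 Arg2:T7
R4	ADE Arg1:T10 Arg2:T9
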