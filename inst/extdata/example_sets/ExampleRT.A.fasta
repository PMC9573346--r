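>ExampleRT_A_seed01
KAIDFREKNKRT
>ExampleRT_A_seed02
KAIDFRVLNKRT
>ExampleRT_A_seed03
AAIDFRELNKRT
>ExampleRT_A_seed04
KAVDFREGNKRT
>ExampleRT_A_seed05
KWGDFRELRKRR
>ExampleRT_A_seed06
KAIDFRELNKRV
>ExampleRT_A_seed07
KAIDFRTLNKRF
>ExampleRT_A_seed08
PYIDFRELNKRT
>ExampleRT_A_seed09
KAIDFRELNKRT
>ExampleRT_A_seed10
KAIDHRECNKRT
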