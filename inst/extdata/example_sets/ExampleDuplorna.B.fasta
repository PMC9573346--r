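>ExampleDuplorna_B_seed01
TGEPGTLGGASILN
>ExampleDuplorna_B_seed02
TGVPGTLLGNSILN
>ExampleDuplorna_B_seed03
TGEPGTLLGNSILN
>ExampleDuplorna_B_seed04
TGEPGTLHGNSILN
>ExampleDuplorna_B_seed05
TLEPGTLLGVSILN
>ExampleDuplorna_B_seed06
TGEPGTLLGNSILN
>ExampleDuplorna_B_seed07
TPEFGTLLGNSILN
>ExampleDuplorna_B_seed08
TGEPGTLTGNGILN
>ExampleDuplorna_B_seed09
TGEPGTLEGNSILN
>ExampleDuplorna_B_seed10
TGEPGELLGHSILN
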