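>ExampleDuplorna_A_seed01
PDFSSFDKSQDA
>ExampleDuplorna_A_seed02
SDFLSFDKSQDA
>ExampleDuplorna_A_seed03
SDFSHFDKSQDW
>ExampleDuplorna_A_seed04
SDFRSFDISVDA
>ExampleDuplorna_A_seed05
SDFSSFDKSQDA
>ExampleDuplorna_A_seed06
SDFSSFDKSQRA
>ExampleDuplorna_A_seed07
SDPYSFDKSQDA
>ExampleDuplorna_A_seed08
SDFSGLDKSQDA
>ExampleDuplorna_A_seed09
SDFSSFDKSQDA
>ExampleDuplorna_A_seed10
SDFSSFDKSQDA
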