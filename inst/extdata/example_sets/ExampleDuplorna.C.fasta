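>ExampleDuplorna_C_seed01
MISSYGDDLLIAT
>ExampleDuplorna_C_seed02
MISDYGDDLLIAT
>ExampleDuplorna_C_seed03
MISSYGDDLLIAT
>ExampleDuplorna_C_seed04
MISSYGDDLLKAT
>ExampleDuplorna_C_seed05
NISSYGDDLLIAE
>ExampleDuplorna_C_seed06
MISSYGDDLLIFT
>ExampleDuplorna_C_seed07
MICSVGDDLLIAT
>ExampleDuplorna_C_seed08
MISSYGDDLLIAT
>ExampleDuplorna_C_seed09
MDSSYGDDLYQAT
>ExampleDuplorna_C_seed10
MISSYGDDLLINT
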