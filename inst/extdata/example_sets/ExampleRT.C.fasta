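>ExampleRT_C_seed01
GQYMDDLYVGSDL
>ExampleRT_C_seed02
GLYMDDLYVGSDL
>ExampleRT_C_seed03
GQYMDDLYVGSDL
>ExampleRT_C_seed04
GQDMDDLYVGSDL
>ExampleRT_C_seed05
GQYMDDLYVGSDL
>ExampleRT_C_seed06
GQYMDDLGVGSDL
>ExampleRT_C_seed07
GQYMDDLYVGSDL
>ExampleRT_C_seed08
GQVMDDLYVGALL
>ExampleRT_C_seed09
GQMMDDLYVGSDF
>ExampleRT_C_seed10
GQLMDDEYPMSDL
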