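>ExampleRT_B_seed01
GWKGSRAGFQSSMT
>ExampleRT_B_seed02
GWKGSPASFQSSMN
>ExampleRT_B_seed03
FWKGGPAIFQSSMI
>ExampleRT_B_seed04
GWKGLPAIFQSSMT
>ExampleRT_B_seed05
GKKGSPAIFQSSMT
>ExampleRT_B_seed06
GWKGSPAIFRSSMT
>ExampleRT_B_seed07
GWSGSPAIFQVSMT
>ExampleRT_B_seed08
GWCGGGAIFQSSML
>ExampleRT_B_seed09
GWSGSPAIFGSSTT
>ExampleRT_B_seed10
GWKGSPTKFQSSMT
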