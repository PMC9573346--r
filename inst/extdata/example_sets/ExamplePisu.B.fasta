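>ExamplePisu_B_seed01
GGMPSGSPCTSVKN
>ExamplePisu_B_seed02
GIGPSGSPCTSVLN
>ExamplePisu_B_seed03
GGMESGSPCTSVLN
>ExamplePisu_B_seed04
QYMPSGSPMESVLN
>ExamplePisu_B_seed05
GGMPSGSRCRSVLN
>ExamplePisu_B_seed06
GGMPSGSPCTSVLN
>ExamplePisu_B_seed07
GGMPSGSPHTSVLN
>ExamplePisu_B_seed08
NIMPSGHPCTSGLN
>ExamplePisu_B_seed09
GGMPSGSPCTSPLE
>ExamplePisu_B_seed10
GGMPVGSLCTSVLN
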