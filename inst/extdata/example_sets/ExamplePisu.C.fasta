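>ExamplePisu_C_seed01
STFSYGDDSLISV
>ExamplePisu_C_seed02
NTFSYGDDSLIWV
>ExamplePisu_C_seed03
GTFSYGDDKLHSR
>ExamplePisu_C_seed04
NVLSYGDDSLIIV
>ExamplePisu_C_seed05
NTFSYGDDSLISV
>ExamplePisu_C_seed06
NIPSVGDDDLISV
>ExamplePisu_C_seed07
NTFSYGDDSLKSV
>ExamplePisu_C_seed08
NTISYGDDELISV
>ExamplePisu_C_seed09
NTFSYGDDSGISV
>ExamplePisu_C_seed10
NTFSYGDDSQISV
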