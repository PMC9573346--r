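>ExamplePisu_A_seed01
DYSKFDSTLSPV
>ExamplePisu_A_seed02
DYSKFDSTLNPS
>ExamplePisu_A_seed03
DPSKFDSTASPV
>ExamplePisu_A_seed04
DYPKFDSTTSPV
>ExamplePisu_A_seed05
DYSKFDSTLSPV
>ExamplePisu_A_seed06
DYSKFDSTLSPV
>ExamplePisu_A_seed07
DYSKFDSTLSPV
>ExamplePisu_A_seed08
DYSSFDSTLSMV
>ExamplePisu_A_seed09
DYSLFDSCLSPV
>ExamplePisu_A_seed10
DYSKFDSTLSPV
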