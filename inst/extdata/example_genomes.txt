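# two 5-region circular genomes in GRIMM-style signed gene order
>reference
1 2 3 4 5 $
>example
-1 4 3 -5 -2 $
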