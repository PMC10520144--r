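# small-inversion model: 1-region inversions twice as likely as 2-region
n 5
2/3 (1 -1)
1/3 (1 -2)(-1 2)
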