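name: grey_paper
label_duration: 2.05
plds: [0.200, 0.775, 0.775, 0.775, 1.800, 2.275, 2.475, 2.675, 2.800]
repeats: [4, 4, 4, 4, 4, 4, 4, 4, 4]
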