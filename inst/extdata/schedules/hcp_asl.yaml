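name: hcp_asl
label_duration: 1.5
plds: [0.2, 0.7, 1.2, 1.7, 2.2]
repeats: [6, 6, 6, 10, 15]
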