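gene_a	gene_b
synKR0001a	synKR0001b
synKR0002a	synKR0002b
synKR0003a	synKR0003b
synKR0004a	synKR0004b
synKR0005a	synKR0005b
synKR0006a	synKR0006b
synKR0007a	synKR0007b
synKR0008a	synKR0008b
synKR0009a	synKR0009b
synKR0010a	synKR0010b
synKP0149a	synKP0149b
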