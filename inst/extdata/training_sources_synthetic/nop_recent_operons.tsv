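gene_a	gene_b
synNR0001a	synNR0001b
synNR0002a	synNR0002b
synNR0003a	synNR0003b
synNR0004a	synNR0004b
synNR0005a	synNR0005b
synNR0006a	synNR0006b
synNR0007a	synNR0007b
synNR0008a	synNR0008b
synNR0009a	synNR0009b
synNR0010a	synNR0010b
synNR0011a	synNR0011b
synNR0012a	synNR0012b
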