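gene_a	gene_b
synNP0001a	synNP0001b
synNP0002a	synNP0002b
synNP0003a	synNP0003b
synNP0004a	synNP0004b
synNP0005a	synNP0005b
synNP0006a	synNP0006b
synNP0007a	synNP0007b
synNP0008a	synNP0008b
synNP0009a	synNP0009b
synNP0010a	synNP0010b
synNP0011a	synNP0011b
synNP0012a	synNP0012b
synNP0013a	synNP0013b
synNP0014a	synNP0014b
synNP0015a	synNP0015b
synNP0016a	synNP0016b
synNP0017a	synNP0017b
synNP0018a	synNP0018b
synNP0019a	synNP0019b
synNP0020a	synNP0020b
synNP0021a	synNP0021b
synNP0022a	synNP0022b
synNP0023a	synNP0023b
synNP0024a	synNP0024b
synNP0025a	synNP0025b
synNP0026a	synNP0026b
synNP0027a	synNP0027b
synNP0028a	synNP0028b
synNP0029a	synNP0029b
synNP0030a	synNP0030b
synNP0031a	synNP0031b
synNP0032a	synNP0032b
synNP0033a	synNP0033b
synNP0034a	synNP0034b
synNP0035a	synNP0035b
synNP0036a	synNP0036b
synNP0037a	synNP0037b
synNP0038a	synNP0038b
synNP0039a	synNP0039b
synNP0040a	synNP0040b
synNP0041a	synNP0041b
synNP0042a	synNP0042b
synNP0043a	synNP0043b
synNP0044a	synNP0044b
synNP0045a	synNP0045b
synNP0046a	synNP0046b
synNP0047a	synNP0047b
synNP0048a	synNP0048b
synNP0049a	synNP0049b
synNP0050a	synNP0050b
synNP0051a	synNP0051b
synNP0052a	synNP0052b
synNP0053a	synNP0053b
synNP0054a	synNP0054b
synNP0055a	synNP0055b
synNP0056a	synNP0056b
synNP0057a	synNP0057b
synNP0058a	synNP0058b
synNP0059a	synNP0059b
synNP0060a	synNP0060b
synNP0061a	synNP0061b
synNP0062a	synNP0062b
synNP0063a	synNP0063b
synNP0064a	synNP0064b
synNP0065a	synNP0065b
synNP0066a	synNP0066b
synNP0067a	synNP0067b
synNP0068a	synNP0068b
synNP0069a	synNP0069b
synNP0070a	synNP0070b
synNP0071a	synNP0071b
synNP0072a	synNP0072b
synNP0073a	synNP0073b
synNP0074a	synNP0074b
synNP0075a	synNP0075b
synNP0076a	synNP0076b
synNP0077a	synNP0077b
synNP0078a	synNP0078b
synNP0079a	synNP0079b
synNP0080a	synNP0080b
synNP0081a	synNP0081b
synNP0082a	synNP0082b
synNP0083a	synNP0083b
synNP0084a	synNP0084b
synNP0085a	synNP0085b
synNP0086a	synNP0086b
synNP0087a	synNP0087b
synNP0088a	synNP0088b
synNP0089a	synNP0089b
synNP0090a	synNP0090b
synNP0091a	synNP0091b
synNP0092a	synNP0092b
synNP0093a	synNP0093b
synNP0094a	synNP0094b
synNP0095a	synNP0095b
synNP0096a	synNP0096b
synNP0097a	synNP0097b
synNP0098a	synNP0098b
synNP0099a	synNP0099b
synNP0100a	synNP0100b
synNP0101a	synNP0101b
synNP0102a	synNP0102b
synNP0103a	synNP0103b
synNP0104a	synNP0104b
synNP0105a	synNP0105b
synNP0106a	synNP0106b
synNP0107a	synNP0107b
synNP0108a	synNP0108b
synNP0109a	synNP0109b
synNP0110a	synNP0110b
synNP0111a	synNP0111b
synNP0112a	synNP0112b
synNP0113a	synNP0113b
synNP0114a	synNP0114b
synNP0115a	synNP0115b
synNP0116a	synNP0116b
synNP0117a	synNP0117b
synNP0118a	synNP0118b
synNP0119a	synNP0119b
synKV0001a	synKV0001b
synKV0002a	synKV0002b
synKV0003a	synKV0003b
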