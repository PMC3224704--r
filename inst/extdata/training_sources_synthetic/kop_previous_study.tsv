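gene_a	gene_b
synKP0001a	synKP0001b
synKP0002a	synKP0002b
synKP0003a	synKP0003b
synKP0004a	synKP0004b
synKP0005a	synKP0005b
synKP0006a	synKP0006b
synKP0007a	synKP0007b
synKP0008a	synKP0008b
synKP0009a	synKP0009b
synKP0010a	synKP0010b
synKP0011a	synKP0011b
synKP0012a	synKP0012b
synKP0013a	synKP0013b
synKP0014a	synKP0014b
synKP0015a	synKP0015b
synKP0016a	synKP0016b
synKP0017a	synKP0017b
synKP0018a	synKP0018b
synKP0019a	synKP0019b
synKP0020a	synKP0020b
synKP0021a	synKP0021b
synKP0022a	synKP0022b
synKP0023a	synKP0023b
synKP0024a	synKP0024b
synKP0025a	synKP0025b
synKP0026a	synKP0026b
synKP0027a	synKP0027b
synKP0028a	synKP0028b
synKP0029a	synKP0029b
synKP0030a	synKP0030b
synKP0031a	synKP0031b
synKP0032a	synKP0032b
synKP0033a	synKP0033b
synKP0034a	synKP0034b
synKP0035a	synKP0035b
synKP0036a	synKP0036b
synKP0037a	synKP0037b
synKP0038a	synKP0038b
synKP0039a	synKP0039b
synKP0040a	synKP0040b
synKP0041a	synKP0041b
synKP0042a	synKP0042b
synKP0043a	synKP0043b
synKP0044a	synKP0044b
synKP0045a	synKP0045b
synKP0046a	synKP0046b
synKP0047a	synKP0047b
synKP0048a	synKP0048b
synKP0049a	synKP0049b
synKP0050a	synKP0050b
synKP0051a	synKP0051b
synKP0052a	synKP0052b
synKP0053a	synKP0053b
synKP0054a	synKP0054b
synKP0055a	synKP0055b
synKP0056a	synKP0056b
synKP0057a	synKP0057b
synKP0058a	synKP0058b
synKP0059a	synKP0059b
synKP0060a	synKP0060b
synKP0061a	synKP0061b
synKP0062a	synKP0062b
synKP0063a	synKP0063b
synKP0064a	synKP0064b
synKP0065a	synKP0065b
synKP0066a	synKP0066b
synKP0067a	synKP0067b
synKP0068a	synKP0068b
synKP0069a	synKP0069b
synKP0070a	synKP0070b
synKP0071a	synKP0071b
synKP0072a	synKP0072b
synKP0073a	synKP0073b
synKP0074a	synKP0074b
synKP0075a	synKP0075b
synKP0076a	synKP0076b
synKP0077a	synKP0077b
synKP0078a	synKP0078b
synKP0079a	synKP0079b
synKP0080a	synKP0080b
synKP0081a	synKP0081b
synKP0082a	synKP0082b
synKP0083a	synKP0083b
synKP0084a	synKP0084b
synKP0085a	synKP0085b
synKP0086a	synKP0086b
synKP0087a	synKP0087b
synKP0088a	synKP0088b
synKP0089a	synKP0089b
synKP0090a	synKP0090b
synKP0091a	synKP0091b
synKP0092a	synKP0092b
synKP0093a	synKP0093b
synKP0094a	synKP0094b
synKP0095a	synKP0095b
synKP0096a	synKP0096b
synKP0097a	synKP0097b
synKP0098a	synKP0098b
synKP0099a	synKP0099b
synKP0100a	synKP0100b
synKP0101a	synKP0101b
synKP0102a	synKP0102b
synKP0103a	synKP0103b
synKP0104a	synKP0104b
synKP0105a	synKP0105b
synKP0106a	synKP0106b
synKP0107a	synKP0107b
synKP0108a	synKP0108b
synKP0109a	synKP0109b
synKP0110a	synKP0110b
synKP0111a	synKP0111b
synKP0112a	synKP0112b
synKP0113a	synKP0113b
synKP0114a	synKP0114b
synKP0115a	synKP0115b
synKP0116a	synKP0116b
synKP0117a	synKP0117b
synKP0118a	synKP0118b
synKP0119a	synKP0119b
synKP0120a	synKP0120b
synKP0121a	synKP0121b
synKP0122a	synKP0122b
synKP0123a	synKP0123b
synKP0124a	synKP0124b
synKP0125a	synKP0125b
synKP0126a	synKP0126b
synKP0127a	synKP0127b
synKP0128a	synKP0128b
synKP0129a	synKP0129b
synKP0130a	synKP0130b
synKP0131a	synKP0131b
synKP0132a	synKP0132b
synKP0133a	synKP0133b
synKP0134a	synKP0134b
synKP0135a	synKP0135b
synKP0136a	synKP0136b
synKP0137a	synKP0137b
synKP0138a	synKP0138b
synKP0139a	synKP0139b
synKP0140a	synKP0140b
synKP0141a	synKP0141b
synKP0142a	synKP0142b
synKP0143a	synKP0143b
synKP0144a	synKP0144b
synKP0145a	synKP0145b
synKP0146a	synKP0146b
synKP0147a	synKP0147b
synKP0148a	synKP0148b
synKP0149a	synKP0149b
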