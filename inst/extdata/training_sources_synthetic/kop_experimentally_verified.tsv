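gene_a	gene_b
synKV0001a	synKV0001b
synKV0002a	synKV0002b
synKV0003a	synKV0003b
synKV0004a	synKV0004b
synKV0005a	synKV0005b
synKV0006a	synKV0006b
synKV0007a	synKV0007b
synKV0008a	synKV0008b
synKV0009a	synKV0009b
synKV0010a	synKV0010b
synKV0011a	synKV0011b
synKV0012a	synKV0012b
synKV0013a	synKV0013b
synKV0014a	synKV0014b
synKV0015a	synKV0015b
synKV0016a	synKV0016b
synKV0017a	synKV0017b
synKV0018a	synKV0018b
synKV0019a	synKV0019b
synKV0020a	synKV0020b
synKV0021a	synKV0021b
synKV0022a	synKV0022b
synKV0023a	synKV0023b
synKV0024a	synKV0024b
synKV0025a	synKV0025b
synKV0026a	synKV0026b
synKV0027a	synKV0027b
synKV0028a	synKV0028b
synKV0029a	synKV0029b
synKV0030a	synKV0030b
synKV0031a	synKV0031b
synKV0032a	synKV0032b
synKV0033a	synKV0033b
synKV0034a	synKV0034b
synKV0035a	synKV0035b
synKV0036a	synKV0036b
synKV0037a	synKV0037b
synKV0038a	synKV0038b
synKV0039a	synKV0039b
synKV0040a	synKV0040b
synKV0041a	synKV0041b
synKV0042a	synKV0042b
synKV0043a	synKV0043b
synKV0044a	synKV0044b
synKV0045a	synKV0045b
synKV0046a	synKV0046b
synKV0047a	synKV0047b
synKV0048a	synKV0048b
synKV0049a	synKV0049b
synKV0050a	synKV0050b
synKV0051a	synKV0051b
synKV0052a	synKV0052b
synKV0053a	synKV0053b
synKV0054a	synKV0054b
synKV0055a	synKV0055b
synKV0056a	synKV0056b
synKV0057a	synKV0057b
synKV0058a	synKV0058b
synKV0059a	synKV0059b
synKV0060a	synKV0060b
synKV0061a	synKV0061b
synKV0062a	synKV0062b
synKV0063a	synKV0063b
synKV0064a	synKV0064b
synKV0065a	synKV0065b
synKV0066a	synKV0066b
synKV0067a	synKV0067b
synKV0068a	synKV0068b
synKV0069a	synKV0069b
synKV0070a	synKV0070b
synKV0071a	synKV0071b
synKV0072a	synKV0072b
synKV0073a	synKV0073b
synKV0074a	synKV0074b
synKV0075a	synKV0075b
synKV0076a	synKV0076b
synKV0077a	synKV0077b
synKV0078a	synKV0078b
synKV0079a	synKV0079b
synKV0080a	synKV0080b
synKV0081a	synKV0081b
synKV0082a	synKV0082b
synKV0083a	synKV0083b
synKV0084a	synKV0084b
synKV0085a	synKV0085b
synKV0086a	synKV0086b
synKV0087a	synKV0087b
synKV0088a	synKV0088b
synKV0089a	synKV0089b
synKV0090a	synKV0090b
synKV0091a	synKV0091b
synKV0092a	synKV0092b
synKV0093a	synKV0093b
synKV0094a	synKV0094b
synKV0095a	synKV0095b
synKV0096a	synKV0096b
synKV0097a	synKV0097b
synKV0098a	synKV0098b
synKV0099a	synKV0099b
synKV0100a	synKV0100b
synKV0101a	synKV0101b
synKV0102a	synKV0102b
synKV0103a	synKV0103b
synKV0104a	synKV0104b
synKV0105a	synKV0105b
synKV0106a	synKV0106b
synKV0107a	synKV0107b
synKV0108a	synKV0108b
synKV0109a	synKV0109b
synKV0110a	synKV0110b
synKV0111a	synKV0111b
synKV0112a	synKV0112b
synKV0113a	synKV0113b
synKV0114a	synKV0114b
synKV0115a	synKV0115b
synKV0116a	synKV0116b
synKV0117a	synKV0117b
synKV0118a	synKV0118b
synKV0119a	synKV0119b
synKV0120a	synKV0120b
synKV0121a	synKV0121b
synKV0122a	synKV0122b
synKV0123a	synKV0123b
synKV0124a	synKV0124b
synKV0125a	synKV0125b
synKV0126a	synKV0126b
synKV0127a	synKV0127b
synKV0128a	synKV0128b
synKV0129a	synKV0129b
synKV0130a	synKV0130b
synKV0131a	synKV0131b
synKV0132a	synKV0132b
synKV0133a	synKV0133b
synKV0134a	synKV0134b
synKV0135a	synKV0135b
synKV0136a	synKV0136b
synKV0137a	synKV0137b
synKV0138a	synKV0138b
synKV0139a	synKV0139b
synKV0140a	synKV0140b
synKV0141a	synKV0141b
synKV0142a	synKV0142b
synKV0143a	synKV0143b
synKV0144a	synKV0144b
synKV0145a	synKV0145b
synKV0146a	synKV0146b
synKV0147a	synKV0147b
synKV0148a	synKV0148b
synKV0149a	synKV0149b
synKV0150a	synKV0150b
synKV0151a	synKV0151b
synKV0152a	synKV0152b
synKV0153a	synKV0153b
synKV0154a	synKV0154b
synKV0155a	synKV0155b
synKV0156a	synKV0156b
synKV0157a	synKV0157b
synKV0158a	synKV0158b
synKV0159a	synKV0159b
synKV0160a	synKV0160b
synKV0161a	synKV0161b
synKV0162a	synKV0162b
synKV0163a	synKV0163b
synKV0164a	synKV0164b
synKV0165a	synKV0165b
synKV0166a	synKV0166b
synKV0167a	synKV0167b
synKV0168a	synKV0168b
synKV0169a	synKV0169b
synKV0170a	synKV0170b
synKV0171a	synKV0171b
synKV0172a	synKV0172b
synKV0173a	synKV0173b
synKV0174a	synKV0174b
synKV0175a	synKV0175b
synKV0176a	synKV0176b
synKV0177a	synKV0177b
synKV0178a	synKV0178b
synKV0179a	synKV0179b
synKV0180a	synKV0180b
synKV0181a	synKV0181b
synKV0182a	synKV0182b
synKV0183a	synKV0183b
synKV0184a	synKV0184b
synKV0185a	synKV0185b
synKV0186a	synKV0186b
synKV0187a	synKV0187b
synKV0188a	synKV0188b
synKV0189a	synKV0189b
synKV0190a	synKV0190b
synKV0191a	synKV0191b
synKV0192a	synKV0192b
synKV0193a	synKV0193b
synKV0194a	synKV0194b
synKV0195a	synKV0195b
synKV0196a	synKV0196b
synKV0197a	synKV0197b
synKV0198a	synKV0198b
synKV0199a	synKV0199b
synKV0200a	synKV0200b
synKV0201a	synKV0201b
synKV0202a	synKV0202b
synKV0203a	synKV0203b
synKV0204a	synKV0204b
synKV0205a	synKV0205b
synKV0206a	synKV0206b
synKV0207a	synKV0207b
synKV0208a	synKV0208b
synKV0209a	synKV0209b
synKV0210a	synKV0210b
synKV0211a	synKV0211b
synKV0212a	synKV0212b
synKV0213a	synKV0213b
synKV0214a	synKV0214b
synKV0215a	synKV0215b
synKV0216a	synKV0216b
synKV0217a	synKV0217b
synKV0218a	synKV0218b
synKV0219a	synKV0219b
synKV0220a	synKV0220b
synKV0221a	synKV0221b
synKV0222a	synKV0222b
synKV0223a	synKV0223b
synKV0224a	synKV0224b
synKV0225a	synKV0225b
synKV0226a	synKV0226b
synKV0227a	synKV0227b
synKV0228a	synKV0228b
synKV0229a	synKV0229b
synKV0230a	synKV0230b
synKV0231a	synKV0231b
synKV0232a	synKV0232b
synKV0233a	synKV0233b
synKV0234a	synKV0234b
synKV0235a	synKV0235b
synKV0236a	synKV0236b
synKV0237a	synKV0237b
synKV0238a	synKV0238b
synKV0239a	synKV0239b
synKV0240a	synKV0240b
synKV0241a	synKV0241b
synKV0242a	synKV0242b
synKV0243a	synKV0243b
synKV0244a	synKV0244b
synKV0245a	synKV0245b
synKV0246a	synKV0246b
synKV0247a	synKV0247b
synKV0248a	synKV0248b
synKV0249a	synKV0249b
synKV0250a	synKV0250b
synKV0251a	synKV0251b
synKV0252a	synKV0252b
synKV0253a	synKV0253b
synKV0254a	synKV0254b
synKV0255a	synKV0255b
synKV0256a	synKV0256b
synKV0257a	synKV0257b
synKV0258a	synKV0258b
synKV0259a	synKV0259b
synKV0260a	synKV0260b
synKV0261a	synKV0261b
synKV0262a	synKV0262b
synKV0263a	synKV0263b
synKV0264a	synKV0264b
synKV0265a	synKV0265b
synKV0266a	synKV0266b
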