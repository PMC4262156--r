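((((Pelusios:60.375,Pelomedusa:60.375)Pelomedusidae:55.075,Podocnemis:115.45)Pelomedusoides:22.65,((Chelodina:56.625,Elseya:56.625)Chelodininae:45.025,(Chelus:57.525,Phrynops:57.525)Chelus_Phrynops:44.125)Chelidae:36.45)Pleurodira:65.4,(((Apalone:80.175,Pelodiscus:80.175)Trionychidae:62.875,Carettochelys:143.05)Trionychia:19.05,(((Chelonia:71.4625,Dermochelys:71.4625)Chelonioidea:23.0625,(Chelydra:82.2625,((Kinosternon:64.465625,Sternotherus:64.465625)Kinosternidae:11.665625,Dermatemys:76.13125)Kinosternoidea:6.13125)Chelydroidea:12.2625)Americhelydia:24.525,(((Chrysemys:45.16875,(Graptemys:18.5,Trachemys:18.5)Graptemys_Trachemys:26.66875)Emydidae:13.16875,Platysternon:58.3375)Emydidae_Platysternon:26.3375,((Heosemys:35.55,Mauremys:35.55)Heosemys_Mauremys:31.9375,Testudo:67.4875)Testuguria:17.1875)Testudinoidea:34.375)Durocryptodira:43.05)Cryptodira:41.4)Testudines;
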