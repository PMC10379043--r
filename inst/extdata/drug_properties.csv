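name,BP,MR,Id2
Aminopterin,782.27,114,3.2656
Aspidostomide E,798.8,116,3.0354
Carmustine,309.6,46.6,2.2456
Caulibugulone E,373,52.2,2.4413
Convolutamine F,629.9,130.1,3.2006
Convolutamydine A,387.7,73.8,2.4587
Tambjamine K,504.9,68.2,2.5088
Deguelin,770,130,3.3387
Perfragilin A,560.1,105.1,3.1628
Melatonin,512.8,67.6,2.6596
Minocycline,803.3,116,3.1999
Podophyllotoxin,431.5,63.6,2.5523
Pterocellin B,597.9,104.3,3.2134
Daunorubicin,521.6,87.4,3.0304
Convolutamide A,728.2,136.6,3.3907
Raloxifene,391.7,76.6,2.784
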