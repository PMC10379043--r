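name,Id2,BP,Epi
BHC1,2.2338,218,13.6832
BHC2,2.5603,338,19.4483
BHC3,2.5603,340,19.3137
BHC4,2.8094,431,25.1922
BHC5,2.8094,425,25.1012
BHC6,2.8094,429,25.2745
BHC7,2.8094,440,24.9308
BHC8,2.9146,496,28.222
BHC9,2.9146,493,28.3361
BHC10,2.9146,497,28.2453
BHC11,3.0121,547,31.2529
BHC12,3.0121,542,31.4251
BHC13,3.0096,535,30.9418
BHC14,3.0096,536,30.8805
BHC15,3.0096,531,30.8795
BHC16,3.0096,519,30.9432
BHC17,3.1021,590,34.5718
BHC18,3.0974,592,34.0646
BHC19,3.097,596,33.1892
BHC20,3.0974,594,33.9542
BHC21,3.0974,595,34.0307
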