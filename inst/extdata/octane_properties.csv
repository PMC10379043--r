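name,compound,S,HVAP,DHVAP,AF,Id2
C8:01,n-octane,111.67,73.19,9.915,0.3979,1.9784
C8:02,2-methylheptane,109.84,70.3,9.484,0.3779,1.8338
C8:03,3-methylheptane,111.26,71.3,9.521,0.371,1.8337
C8:04,4-methylheptane,109.32,70.91,9.483,0.3715,1.8338
C8:05,3-ethylhexane,109.43,71.7,9.476,0.3625,1.8338
C8:06,"2,2-dimethylhexane",103.42,67.7,8.915,0.3394,1.5596
C8:07,"2,3-dimethylhexane",108.02,70.2,9.272,0.3482,1.7132
C8:08,"2,4-dimethylhexane",106.98,68.5,9.029,0.3442,1.7132
C8:09,"2,5-dimethylhexane",105.72,68.6,9.051,0.3568,1.7132
C8:10,"3,3-dimethylhexane",104.74,68.5,8.973,0.3225,1.5596
C8:11,"3,4-dimethylhexane",106.59,70.2,9.316,0.3403,1.7132
C8:12,2-methyl-3-ethylpentane,106.06,69.7,9.209,0.3324,1.7132
C8:13,3-methyl-3-ethylpentane,101.48,69.3,9.081,0.3067,1.5596
C8:14,"2,2,3-trimethylpentane",101.31,67.3,8.826,0.3008,1.4769
C8:15,"2,2,4-trimethylpentane",104.09,64.87,8.402,0.3054,1.4769
C8:16,"2,3,3-trimethylpentane",102.06,68.1,8.897,0.2932,1.4769
C8:17,"2,3,4-trimethylpentane",102.39,68.37,9.014,0.3174,1.6118
C8:18,"2,2,3,3-tetramethylbutane",93.06,66.2,8.41,0.2552,1.3028
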