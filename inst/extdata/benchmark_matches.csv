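dataset,complex_strong,affinity_strong_nM,complex_weak,affinity_weak_nM,matches
1,1xn2,0.03,1xn3,40,5
1,2qlf,1.4,2qlb,1300,3
1,2r5d,0.07,2r5b,2.5,3
1,2w6t,2.7,2w6u,10000,5
1,2axi,5,2gv2,140,5
1,3er5,14,4er4,160,4
2,2aoj,22100,2aoi,96700,4
2,2h5i,1.3,2h5j,12.4,1
2,6m9f,6,6m8y,415,4
2,2w16,0.1,2w78,2.7,3
2,3ove,270,3ov1,6250,4
2,1a1c,400,1a08,2400,4
2,1jyq,2,1zfp,26,3
2,4er2,0.5,2er9,40,5
2,5apr,17,4apr,200,4
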