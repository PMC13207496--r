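client,total,n_normal,n_benign,n_malignant,pct_normal,pct_benign,pct_malignant
1,3247,1250,1111,886,38.5,34.2,27.3
2,2541,714,1215,612,28.1,47.8,24.1
3,1823,408,720,695,22.4,39.5,38.1
4,2106,870,884,352,41.3,42.0,16.7
5,1652,747,671,234,45.2,40.6,14.2
6,847,260,325,262,30.7,38.4,30.9
7,1934,534,853,547,27.6,44.1,28.3
8,1697,609,738,350,35.9,43.5,20.6
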