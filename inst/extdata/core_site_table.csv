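patch_id,area_km2,protected_areas,printed_males,printed_females
1,10054.10,Cibagou NNR,23,66
2,7518.06,"Giant Panda NP; Heizhugou NNR; Mabian Dafengding NNR; Meigu Dafengding NNR; Bayuelin NR; Mamize NR; Maanshan NR",17,49
3,7002.50,Giant Panda NP,16,46
4,3667.27,,8,23
5,3608.42,,8,23
6,2769.58,"Wuyishan NP; Tongbo mountain NR",6,18
7,2736.27,"Giant Panda NP; Jiuzhaigou NR",6,18
8,2619.86,Jiulongshan NNR,5,17
9,2311.22,Baima Snow Mountain NNR,5,15
10,1995.02,"Huaping NNR; Maoershan NNR; Nanshan NP",4,13
11,1932.74,Giant Panda NP,4,12
12,1433.13,"Bamian Mountain NNR; Taoyuandong NNR; Jinggangshan NNR",3,9
13,1234.82,,2,8
14,1091.61,Gaoligong Mountain NNR,2,7
15,1078.57,Meihuashan NNR,2,7
16,1021.09,,2,6
17,1018.29,Yarlung Zangbo Grand Canyon NNR,2,6
18,991.45,"Hubeishan NNR; Houhe NNR; Mulinzi NNR",2,6
19,925.61,"Nanling NNR; Mangshan NNR",2,6
20,793.57,"Qizimei Mountain NNR; Badagongshan NNR",1,5
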