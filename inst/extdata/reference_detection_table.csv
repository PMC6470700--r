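volunteer,sex,age_yr,weight_kg,height_cm,position,avg_hr_bpm,n_detectable,n_not_correct,n_false_positive,pct_correct
1,M,31,83,180,supine,76,1050,19,0,98.2
1,M,31,83,180,prone,64,872,100,0,88.6
1,M,31,83,180,left_lateral,69,944,32,0,96.6
1,M,31,83,180,right_lateral,68,928,18,0,98.0
2,M,35,78,180,supine,39,502,29,8,94.3
2,M,35,78,180,prone,41,524,19,4,96.4
2,M,35,78,180,left_lateral,38,486,43,8,91.2
2,M,35,78,180,right_lateral,43,551,55,7,90.0
3,M,28,75,170,supine,53,700,65,1,90.7
3,M,28,75,170,prone,56,756,149,5,80.5
3,M,28,75,170,left_lateral,57,758,37,2,95.0
3,M,28,75,170,right_lateral,61,822,204,3,74.8
4,M,30,78,170,supine,87,1211,200,0,83.5
4,M,30,78,170,prone,83,1151,285,0,75.2
4,M,30,78,170,left_lateral,79,1089,67,1,93.9
4,M,30,78,170,right_lateral,82,1142,59,0,94.9
5,M,26,65,170,supine,59,802,75,1,90.7
5,M,26,65,170,prone,61,828,29,0,96.5
5,M,26,65,170,left_lateral,63,853,94,1,88.9
5,M,26,65,170,right_lateral,61,822,252,5,69.3
6,M,30,95,173,supine,84,1177,383,0,67.4
6,M,30,95,173,prone,88,1235,500,1,59.8
6,M,30,95,173,left_lateral,83,1150,173,0,84.9
6,M,30,95,173,right_lateral,86,1206,473,0,60.8
7,F,70,67,158,supine,68,926,615,9,33.6
7,F,70,67,158,prone,70,958,186,4,80.6
7,F,70,67,158,left_lateral,65,879,117,36,86.7
7,F,70,67,158,right_lateral,67,921,109,12,88.1
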