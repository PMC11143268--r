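"tree_id","plot_id","species_id","phenology","dbh_prev_cm","dbh_curr_cm","fate"
"keep12_1","keep12","sp_a","EV",20,21,"survivor"
"keep12_2","keep12","sp_b","DE",20,21,"survivor"
"keep12_3","keep12","sp_a","EV",20,21,"survivor"
"keep12_4","keep12","sp_b","DE",20,21,"survivor"
"keep12_5","keep12","sp_a","EV",20,21,"survivor"
"keep12_6","keep12","sp_b","DE",20,21,"survivor"
"keep12_7","keep12","sp_a","EV",20,21,"survivor"
"keep12_8","keep12","sp_b","DE",20,21,"survivor"
"keep12_9","keep12","sp_a","EV",20,21,"survivor"
"keep12_10","keep12","sp_b","DE",20,21,"survivor"
"keep12_11","keep12","sp_a","EV",20,21,"survivor"
"keep12_12","keep12","sp_b","DE",20,21,"survivor"
"small9_1","small9","sp_a","EV",20,21,"survivor"
"small9_2","small9","sp_b","DE",20,21,"survivor"
"small9_3","small9","sp_a","EV",20,21,"survivor"
"small9_4","small9","sp_b","DE",20,21,"survivor"
"small9_5","small9","sp_a","EV",20,21,"survivor"
"small9_6","small9","sp_b","DE",20,21,"survivor"
"small9_7","small9","sp_a","EV",20,21,"survivor"
"small9_8","small9","sp_b","DE",20,21,"survivor"
"small9_9","small9","sp_a","EV",20,21,"survivor"
"dead15_1","dead15","sp_a","EV",20,NA,"died"
"dead15_2","dead15","sp_b","DE",20,NA,"died"
"dead15_3","dead15","sp_a","EV",20,NA,"died"
"dead15_4","dead15","sp_b","DE",20,NA,"died"
"dead15_5","dead15","sp_a","EV",20,NA,"died"
"dead15_6","dead15","sp_b","DE",20,NA,"died"
"dead15_7","dead15","sp_a","EV",20,NA,"died"
"dead15_8","dead15","sp_b","DE",20,NA,"died"
"dead15_9","dead15","sp_a","EV",20,NA,"died"
"dead15_10","dead15","sp_b","DE",20,21,"survivor"
"dead15_11","dead15","sp_a","EV",20,21,"survivor"
"dead15_12","dead15","sp_b","DE",20,21,"survivor"
"dead15_13","dead15","sp_a","EV",20,21,"survivor"
"dead15_14","dead15","sp_b","DE",20,21,"survivor"
"dead15_15","dead15","sp_a","EV",20,21,"survivor"
"mono20_1","mono20","sp_a","EV",20,21,"survivor"
"mono20_2","mono20","sp_a","DE",20,21,"survivor"
"mono20_3","mono20","sp_a","EV",20,21,"survivor"
"mono20_4","mono20","sp_a","DE",20,21,"survivor"
"mono20_5","mono20","sp_a","EV",20,21,"survivor"
"mono20_6","mono20","sp_a","DE",20,21,"survivor"
"mono20_7","mono20","sp_a","EV",20,21,"survivor"
"mono20_8","mono20","sp_a","DE",20,21,"survivor"
"mono20_9","mono20","sp_a","EV",20,21,"survivor"
"mono20_10","mono20","sp_a","DE",20,21,"survivor"
"mono20_11","mono20","sp_a","EV",20,21,"survivor"
"mono20_12","mono20","sp_a","DE",20,21,"survivor"
"mono20_13","mono20","sp_a","EV",20,21,"survivor"
"mono20_14","mono20","sp_a","DE",20,21,"survivor"
"mono20_15","mono20","sp_a","EV",20,21,"survivor"
"mono20_16","mono20","sp_a","DE",20,21,"survivor"
"mono20_17","mono20","sp_a","EV",20,21,"survivor"
"mono20_18","mono20","sp_a","DE",20,21,"survivor"
"mono20_19","mono20","sp_a","EV",20,21,"survivor"
"mono20_20","mono20","sp_a","DE",20,21,"survivor"
"keep11_1","keep11","sp_a","EV",20,21,"survivor"
"keep11_2","keep11","sp_b","DE",20,21,"survivor"
"keep11_3","keep11","sp_a","EV",20,21,"survivor"
"keep11_4","keep11","sp_b","DE",20,21,"survivor"
"keep11_5","keep11","sp_a","EV",20,21,"survivor"
"keep11_6","keep11","sp_b","DE",20,21,"survivor"
"keep11_7","keep11","sp_a","EV",20,21,"survivor"
"keep11_8","keep11","sp_b","DE",20,21,"survivor"
"keep11_9","keep11","sp_a","EV",20,21,"survivor"
"keep11_10","keep11","sp_b","DE",20,21,"survivor"
"keep11_11","keep11","sp_a","EV",20,21,"survivor"
"dom30_1","dom30","sp_a","EV",30,31,"survivor"
"dom30_2","dom30","sp_a","DE",30,31,"survivor"
"dom30_3","dom30","sp_a","EV",30,31,"survivor"
"dom30_4","dom30","sp_a","DE",30,31,"survivor"
"dom30_5","dom30","sp_a","EV",30,31,"survivor"
"dom30_6","dom30","sp_a","DE",30,31,"survivor"
"dom30_7","dom30","sp_a","EV",30,31,"survivor"
"dom30_8","dom30","sp_a","DE",30,31,"survivor"
"dom30_9","dom30","sp_a","EV",30,31,"survivor"
"dom30_10","dom30","sp_a","DE",30,31,"survivor"
"dom30_11","dom30","sp_a","EV",30,31,"survivor"
"dom30_12","dom30","sp_a","DE",30,31,"survivor"
"dom30_13","dom30","sp_a","EV",30,31,"survivor"
"dom30_14","dom30","sp_a","DE",30,31,"survivor"
"dom30_15","dom30","sp_a","EV",30,31,"survivor"
"dom30_16","dom30","sp_a","DE",30,31,"survivor"
"dom30_17","dom30","sp_a","EV",30,31,"survivor"
"dom30_18","dom30","sp_a","DE",30,31,"survivor"
"dom30_19","dom30","sp_a","EV",30,31,"survivor"
"dom30_20","dom30","sp_a","DE",30,31,"survivor"
"dom30_21","dom30","sp_a","EV",30,31,"survivor"
"dom30_22","dom30","sp_a","DE",30,31,"survivor"
"dom30_23","dom30","sp_a","EV",30,31,"survivor"
"dom30_24","dom30","sp_a","DE",30,31,"survivor"
"dom30_25","dom30","sp_a","EV",30,31,"survivor"
"dom30_26","dom30","sp_a","DE",30,31,"survivor"
"dom30_27","dom30","sp_a","EV",30,31,"survivor"
"dom30_28","dom30","sp_a","DE",30,31,"survivor"
"dom30_29","dom30","sp_a","EV",30,31,"survivor"
"dom30_30","dom30","sp_b","DE",10,11,"survivor"
"keep14_1","keep14","sp_a","EV",20,21,"survivor"
"keep14_2","keep14","sp_b","DE",20,21,"survivor"
"keep14_3","keep14","sp_a","EV",20,21,"survivor"
"keep14_4","keep14","sp_b","DE",20,21,"survivor"
"keep14_5","keep14","sp_a","EV",20,21,"survivor"
"keep14_6","keep14","sp_b","DE",20,21,"survivor"
"keep14_7","keep14","sp_a","EV",20,21,"survivor"
"keep14_8","keep14","sp_b","DE",20,21,"survivor"
"keep14_9","keep14","sp_a","EV",20,21,"survivor"
"keep14_10","keep14","sp_b","DE",20,21,"survivor"
"keep14_11","keep14","sp_a","EV",20,21,"survivor"
"keep14_12","keep14","sp_b","DE",20,21,"survivor"
"keep14_13","keep14","sp_a","EV",20,21,"survivor"
"keep14_14","keep14","sp_b","DE",20,21,"survivor"
"unk10_1","unk10","sp_a","UNKNOWN",25,26,"survivor"
"unk10_2","unk10","sp_b","UNKNOWN",25,26,"survivor"
"unk10_3","unk10","sp_a","EV",17.3,18.3,"survivor"
"unk10_4","unk10","sp_b","EV",17.3,18.3,"survivor"
"unk10_5","unk10","sp_a","EV",17.3,18.3,"survivor"
"unk10_6","unk10","sp_b","EV",17.3,18.3,"survivor"
"unk10_7","unk10","sp_a","DE",17.3,18.3,"survivor"
"unk10_8","unk10","sp_b","DE",17.3,18.3,"survivor"
"unk10_9","unk10","sp_a","DE",17.3,18.3,"survivor"
"unk10_10","unk10","sp_b","DE",17.3,18.3,"survivor"
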