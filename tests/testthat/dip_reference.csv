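id,n,type,dip
  1,195,uniform,0.034816973671195010
  2, 63,bimodal,0.151132757178881277
  3,162,weak_bimodal,0.019768264861265015
  4,179,gamma,0.017918621432488284
  5,171,normal,0.020520937632157218
  6,147,uniform,0.033043798993217410
  7,190,bimodal,0.139960020582910044
  8,193,weak_bimodal,0.023630843367306132
  9,108,gamma,0.023313795283129362
 10,124,normal,0.021422460696879097
 11,113,uniform,0.036485955200595901
 12,155,bimodal,0.149033775211268343
 13,122,weak_bimodal,0.047131561405969268
 14,189,gamma,0.015387993219466857
 15,133,normal,0.017589352276088030
 16, 64,uniform,0.043807239802349310
 17, 83,bimodal,0.143689404927615116
 18,112,weak_bimodal,0.021582250959042544
 19,189,gamma,0.017452214535173049
 20,194,normal,0.017614286195046722
 21, 88,uniform,0.035207247756340140
 22,132,bimodal,0.130632964486497777
 23,174,weak_bimodal,0.032840561196531406
 24,141,gamma,0.026685126313266593
 25,120,normal,0.022872567020277238
 26,137,uniform,0.031770006900896097
 27,149,bimodal,0.136147240826137078
 28, 74,weak_bimodal,0.032517466710900465
 29,180,gamma,0.019372864344959922
 30, 54,normal,0.049575283987178635
 31, 82,uniform,0.047627222094815735
 32, 86,bimodal,0.154869592600653000
 33,111,weak_bimodal,0.021881610383422928
 34,115,gamma,0.020555362050175642
 35, 96,normal,0.031139461265115870
 36,152,uniform,0.029927678568820292
 37,130,bimodal,0.120255740868046496
 38,121,weak_bimodal,0.028669479992706432
 39,169,gamma,0.018865901987363341
 40,113,normal,0.024945927239959153
 41,171,uniform,0.028127340061689841
 42,180,bimodal,0.128232866639580112
 43,196,weak_bimodal,0.025577559459704108
 44,189,gamma,0.016813817916658425
 45, 68,normal,0.033679817596819060
 46,183,uniform,0.016950929814453210
 47,134,bimodal,0.128078629782964748
 48,192,weak_bimodal,0.017055877468512989
 49,169,gamma,0.022539549945823557
 50, 52,normal,0.041158552559064615
 51,105,uniform,0.038688879584223977
 52, 99,bimodal,0.133338540344240808
 53,143,weak_bimodal,0.033641743993871501
 54,150,gamma,0.019194716755056535
 55,141,normal,0.033116403411861485
 56,110,uniform,0.027876320206250728
 57, 51,bimodal,0.152728466874084673
 58,199,weak_bimodal,0.024600755373159651
 59,152,gamma,0.017567692534953078
 60, 87,normal,0.036010900285923200
 61, 74,uniform,0.034468738657194485
 62,155,bimodal,0.129984598975935811
 63, 92,weak_bimodal,0.027626580771572085
 64, 85,gamma,0.027058692752253762
 65,193,normal,0.013749338139236088
 66, 78,uniform,0.051333057660921298
 67,142,bimodal,0.119061187814137784
 68, 74,weak_bimodal,0.045008557871185739
 69,101,gamma,0.030246921110819565
 70, 72,normal,0.043848392127484384
 71, 80,uniform,0.054418046903692209
 72,114,bimodal,0.144938320630512818
 73,170,weak_bimodal,0.037913258439018174
 74, 86,gamma,0.024038388661956844
 75, 60,normal,0.037138568072914033
 76, 76,uniform,0.034527587112972234
 77, 86,bimodal,0.142251688260809334
 78,162,weak_bimodal,0.022266501290914346
 79,137,gamma,0.033976804889581672
 80,124,normal,0.023521924278543917
 81,169,uniform,0.023258012008866822
 82, 88,bimodal,0.150012822207715502
 83,191,weak_bimodal,0.019514475409756767
 84,128,gamma,0.031020212529309352
 85,146,normal,0.018995271561494685
 86, 65,uniform,0.045314716357344138
 87, 88,bimodal,0.124527358578387690
 88, 54,weak_bimodal,0.049323620886946647
 89, 99,gamma,0.030624157726322425
 90, 73,normal,0.040087945532698219
 91,164,uniform,0.029669691493205735
 92, 96,bimodal,0.142984541305516383
 93, 91,weak_bimodal,0.041907868667361098
 94, 64,gamma,0.039485538757280739
 95,135,normal,0.026285774283031974
 96,141,uniform,0.020354621960108257
 97,180,bimodal,0.135904920721516942
 98,136,weak_bimodal,0.030256544601279703
 99, 87,gamma,0.037103143416163976
100,180,normal,0.026275520960703316
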