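transcript_id	sample_id	depths
TX01	FFPE_A	1,2,4,1,4,4,2,2,0,1,1,3,1,3,2,3,6,1,3,4,1,2,0,1,1,0,1,4,1,2,2,2,1,3,2,3,0,3,2,3
TX02	FFPE_A	10,8,8,10,3,8,10,9,8,11,7,6,4,4,7,8,9,7,12,6,8,7,9,6,8,10,4,11,7,11,7,7,8,12,11,7,10,13,7,9
TX03	FFPE_A	22,27,21,17,28,24,29,26,21,21,32,34,23,19,18,37,24,28,25,21,17,32,25,35,27,21,24,28,30,25,24,20,22,31,28,23,22,26,30,23
TX04	FFPE_A	10,9,12,6,6,11,8,11,5,10,10,13,8,9,7,5,12,6,8,5,11,7,10,6,6,8,6,5,8,8,5,6,10,13,5,10,13,11,6,9
TX05	FFPE_A	1,1,1,2,4,2,1,0,2,3,1,0,1,2,1,3,3,2,2,2,1,2,4,1,2,1,2,0,2,4,3,4,2,2,2,0,1,2,1,4
TX06	FFPE_A	1,3,3,1,0,3,2,1,0,0,1,1,1,1,1,1,2,3,0,2,4,1,0,1,1,1,0,1,1,0,5,1,2,3,0,0,0,4,2,0
TX01	FFPE_B	24,36,29,23,20,21,23,26,22,30,29,21,22,17,19,36,25,27,24,23,24,28,35,30,31,18,22,17,24,25,21,22,24,25,35,21,18,19,19,22
TX02	FFPE_B	1,5,4,4,3,1,3,0,4,6,1,3,3,3,2,2,1,3,3,2,2,2,1,1,1,0,4,3,4,4,0,1,2,0,3,3,0,2,4,0
TX03	FFPE_B	1,2,1,4,0,0,5,2,1,1,0,2,2,6,2,0,1,2,0,2,1,4,3,1,2,3,2,5,3,1,0,1,4,2,2,3,3,1,3,4
TX04	FFPE_B	25,29,23,24,30,25,27,24,23,28,30,12,20,22,27,19,29,33,26,22,16,20,33,22,38,25,30,13,23,16,26,22,27,26,33,23,18,27,30,23
TX05	FFPE_B	0,2,2,0,2,5,3,2,1,3,2,3,2,2,2,1,2,3,4,1,3,5,5,1,1,5,0,4,1,2,2,3,1,1,1,2,0,3,1,2
TX06	FFPE_B	1,2,1,2,2,4,4,1,1,3,2,1,0,0,3,2,4,1,4,1,3,1,0,4,3,4,2,3,1,1,2,0,1,2,3,4,1,3,0,2
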