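# Synthetic demonstration school sampling frame (40 fictional schools)
# with enrollment and year-group counts. Generated data; no real schools.
school_id,name,enrollment,yg_1,yg_2,yg_3,yg_4,yg_5,yg_6
SCH01,Demo School 01,265,46,39,43,39,57,41
SCH02,Demo School 02,596,99,103,100,113,91,90
SCH03,Demo School 03,339,56,60,55,55,52,61
SCH04,Demo School 04,371,49,66,58,53,74,71
SCH05,Demo School 05,125,19,21,19,24,20,22
SCH06,Demo School 06,111,17,26,18,18,12,20
SCH07,Demo School 07,1450,218,263,244,232,249,244
SCH08,Demo School 08,1249,216,208,206,198,210,211
SCH09,Demo School 09,916,137,160,161,158,153,147
SCH10,Demo School 10,247,44,46,44,45,33,35
SCH11,Demo School 11,189,27,29,35,36,30,32
SCH12,Demo School 12,396,64,76,58,76,60,62
SCH13,Demo School 13,178,41,26,27,27,33,24
SCH14,Demo School 14,407,60,61,65,76,76,69
SCH15,Demo School 15,435,78,64,83,69,72,69
SCH16,Demo School 16,296,44,43,57,54,44,54
SCH17,Demo School 17,1428,207,228,240,236,255,262
SCH18,Demo School 18,1232,194,193,214,209,205,217
SCH19,Demo School 19,1496,249,242,255,240,240,270
SCH20,Demo School 20,235,36,25,35,33,49,57
SCH21,Demo School 21,93,16,9,13,20,18,17
SCH22,Demo School 22,638,96,108,113,105,112,104
SCH23,Demo School 23,184,26,27,39,33,25,34
SCH24,Demo School 24,866,158,132,148,140,144,144
SCH25,Demo School 25,164,20,29,27,30,29,29
SCH26,Demo School 26,437,57,80,77,63,81,79
SCH27,Demo School 27,685,125,102,112,114,120,112
SCH28,Demo School 28,127,18,23,25,23,18,20
SCH29,Demo School 29,1479,247,262,246,251,237,236
SCH30,Demo School 30,135,22,31,27,20,17,18
SCH31,Demo School 31,926,145,181,142,153,143,162
SCH32,Demo School 32,877,152,153,135,150,143,144
SCH33,Demo School 33,72,17,16,16,9,7,7
SCH34,Demo School 34,387,71,55,73,64,64,60
SCH35,Demo School 35,92,18,12,14,12,19,17
SCH36,Demo School 36,975,166,183,154,148,153,171
SCH37,Demo School 37,514,90,96,80,78,83,87
SCH38,Demo School 38,784,137,118,147,142,125,115
SCH39,Demo School 39,697,117,124,93,127,117,119
SCH40,Demo School 40,288,51,43,58,48,40,48
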